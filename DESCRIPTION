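Package: fnirsdrive
Title: Passenger fNIRS Risk Detection and Physiologically Guided
    Reinforcement Learning for Longitudinal Driving
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Online detection of subjectively perceived driving risk from
    functional near-infrared spectroscopy (fNIRS) hemodynamic signals, and
    its use to guide a reinforcement-learning longitudinal driving agent.
    Provides a synthetic fNIRS episode generator with a canonical
    double-gamma hemodynamic response and physiological noise; a real-time
    preprocessing chain (baseline correction, cubic-spline resampling to
    50 Hz, a low-lag band-pass built from the difference of two double
    exponential moving averages with moving-average smoothing, and oxygen
    exchange index computation); Daubechies-4 wavelet feature extraction
    with information-gain feature selection; a six-member soft-voting risk
    classifier with balanced-accuracy evaluation; a lightweight
    longitudinal driving simulator with an intelligent-driver-model (IDM)
    fallback controller; a twin-delayed deep deterministic policy gradient
    (TD3) agent with risk-gated action switching and a behaviour-cloning
    actor term; and trajectory safety and comfort metrics (driving risk
    field, time to collision, jerk) with the associated hypothesis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    nnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
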