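Package: bsnkit
Title: Body Sensor Network Vital-Sign Estimation, Packet Codecs and
    Network Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software re-creation of a remote health-monitoring stack
    for wearable body sensor networks. Provides synthetic physiological
    signal generators with known ground truth (ECG, dual-wavelength
    photoplethysmogram, airflow, tri-axial accelerometer, RTD bridge
    voltage), the corresponding vital-sign estimators (derivative-based
    QRS detection and heart rate, threshold-crossing respiration rate,
    ratio-of-ratios pulse oximetry, Wheatstone-bridge body temperature,
    galvanic skin resistance, three-stage accelerometer fall detection),
    fixed-layout binary packet encoders with AES-128 payload protection,
    a discrete-event simulator of a hierarchical wireless sensor network
    with RSSI/hops/lifetime link metrics and redundant routing, range-free
    centroid indoor localization, and range-based vital-sign alerting with
    JSON record output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    openssl,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
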