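Package: kinerisk
Title: Motion-Capture Kinematics and Muscle Over-Lengthening Injury Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline from labelled 3D marker trajectories to
    muscle injury-risk reports. Reconstructs a 15-segment full-body
    skeleton by least-squares rigid pose fitting, computes Cardan joint
    angles, range of motion and angular velocity, tracks straight-line
    muscle path lengths normalised to their rest length, flags muscles
    whose lengthening exceeds 120 percent of rest length (the repetitive
    stress injury criterion), detects impact-like eccentric loading,
    segments pitching trials into phases, and compares skills with
    independent two-sample t-tests from raw samples or printed summary
    statistics. A forward-kinematics motion generator provides synthetic
    trials with known ground truth for instep kick, fan kick, axe kick
    and baseball pitch.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
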