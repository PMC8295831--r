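Package: headachediary
Title: Classification and Longitudinal Analysis of Electronic Headache Diaries
Version: 0.1.0
Authors@R:
    person("Diary", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing smartphone headache e-diaries: rule-based
    classification of single headache attacks as migraine, tension-type
    headache or other following the International Classification of Headache
    Disorders (ICHD-3); expansion of attacks to calendar days and aggregation
    into 28-day months (monthly headache days, monthly migraine days, monthly
    days with acute medication use, mean intensities); episodic/chronic
    migraine subgrouping from the first 90 days of use; selection of daily-use
    cohorts; paired t tests and repeated-measures ANOVA for baseline versus
    follow-up comparisons; and a seeded synthetic-diary generator with
    closed-form expectations for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
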