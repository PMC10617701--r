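# Frozen per-round generator parameters for round_config().
#
# Covariate model parameters target the published round-specific sample
# composition (education mix, media exposure, HIV testing, sex); the
# outcome coefficients are the published round's marginal effects
# rescaled to the logit scale.  The outcome intercept and the direct
# SES gradient were calibrated once by iterative matching on simulated
# populations (n = 150,000 per iteration, verified at n = 400,000) so
# that the weighted prevalence and Erreygers index of the composite
# indicator hit the published round values; they are shipped as
# constants and are never re-tuned at run time.

.round_params <- list(
  "2005" = list(
    heard_rate = 0.92,
    covariates = list(
      sex = list(kind = "binary", levels = c("women", "men"), prob = 0.29),
      education = list(kind = "ordinal",
                       levels = c("none", "primary", "secondary", "higher"),
                       slope = 1.2, cutpoints = c(0.2328, 2.0312, 4.6325)),
      radio = list(kind = "binary", levels = c("no", "yes"),
                   intercept = 0.103, slope = 0.9),
      tv = list(kind = "binary", levels = c("no", "yes"),
                intercept = -1.5411, slope = 1.8),
      newspaper = list(kind = "binary", levels = c("no", "yes"),
                       intercept = -1.5025, slope = 1.1),
      tested = list(kind = "binary", levels = c("no", "yes"),
                    intercept = -2.8619, slope = 0.6)),
    outcome = list(intercept = -2.3705, z = 0.4297,
                   coefficients = c("sex:men" = 0.47, "residence:urban" = 0.33,
                                    "education:primary" = 0.62,
                                    "education:secondary" = 1.18,
                                    "education:higher" = 1.17,
                                    "radio:yes" = 0.28, "tv:yes" = 0.16,
                                    "newspaper:yes" = 0.19,
                                    "tested:yes" = 0.30))),
  "2011" = list(
    heard_rate = 0.975,
    covariates = list(
      sex = list(kind = "binary", levels = c("women", "men"), prob = 0.44),
      education = list(kind = "ordinal",
                       levels = c("none", "primary", "secondary", "higher"),
                       slope = 1.2, cutpoints = c(-0.6556, 2.1123, 3.2645)),
      radio = list(kind = "binary", levels = c("no", "yes"),
                   intercept = 0.8236, slope = 0.9),
      tv = list(kind = "binary", levels = c("no", "yes"),
                intercept = 0.4147, slope = 1.8),
      newspaper = list(kind = "binary", levels = c("no", "yes"),
                       intercept = -1.0286, slope = 1.1),
      tested = list(kind = "binary", levels = c("no", "yes"),
                    intercept = -0.3583, slope = 0.6)),
    outcome = list(intercept = -2.2291, z = 0.2648,
                   coefficients = c("sex:men" = 0.41, "residence:urban" = 0.14,
                                    "education:primary" = 0.60,
                                    "education:secondary" = 0.94,
                                    "education:higher" = 1.10,
                                    "radio:yes" = 0.27, "tv:yes" = 0.15,
                                    "newspaper:yes" = 0.26,
                                    "tested:yes" = 0.35))),
  "2016" = list(
    heard_rate = 0.95,
    covariates = list(
      sex = list(kind = "binary", levels = c("women", "men"), prob = 0.43),
      education = list(kind = "ordinal",
                       levels = c("none", "primary", "secondary", "higher"),
                       slope = 1.2, cutpoints = c(-0.7819, 1.5672, 3.0322)),
      radio = list(kind = "binary", levels = c("no", "yes"),
                   intercept = -0.2718, slope = 0.9),
      tv = list(kind = "binary", levels = c("no", "yes"),
                intercept = -0.5331, slope = 1.8),
      newspaper = list(kind = "binary", levels = c("no", "yes"),
                       intercept = -1.565, slope = 1.1),
      tested = list(kind = "binary", levels = c("no", "yes"),
                    intercept = -0.1287, slope = 0.6)),
    outcome = list(intercept = -1.8629, z = 0.2149,
                   coefficients = c("sex:men" = 0.58, "residence:urban" = -0.01,
                                    "education:primary" = 0.49,
                                    "education:secondary" = 0.79,
                                    "education:higher" = 1.09,
                                    "radio:yes" = -0.04, "tv:yes" = 0.32,
                                    "newspaper:yes" = 0.11,
                                    "tested:yes" = 0.25))))
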