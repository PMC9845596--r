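# Independent oracles, coded separately from the implementation paths
# they check.

# exact two-sided Mann-Whitney p by full enumeration of all labelings
mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) # U counts x > y pairs
  }
  labelings <- utils::combn(n + m, n)
  u_all <- apply(labelings, 2, u_of)
  u_obs <- sum(outer(x, y, ">"))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# brute-force MS rule: mandatory waist plus >= 2 of the other four
ms_oracle <- function(wc, tg, hdl, bp, gly) {
  total <- wc + tg + hdl + bp + gly
  if (wc && (tg + hdl + bp + gly) >= 2) return("MS")
  if (total >= 1) return("pre_MS")
  "no_criteria"
}

# nested-if OGTT categorisation, precedence DM > IGT > IFG
glyco_oracle <- function(g0, g120, dm2 = FALSE) {
  if (dm2) return("DM")
  if (g0 >= 7.0) return("DM")
  if (g120 >= 11.1) return("DM")
  if (g120 >= 7.8) return("IGT")
  if (g0 >= 5.6) return("IFG")
  "normal"
}

# mean of a normal truncated below at `lower`
tnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

# small fully-observed cohort built by hand (no generator involvement)
make_manual_cohort <- function() {
  data.frame(
    id = sprintf("P%02d", 1:6),
    sex = c("male", "female", "male", "female", "male", "female"),
    age = c(22, 28, 45, 52, 33, 61),
    weight = c(95, 88, 102, 79, 110, 85),
    height = c(178, 165, 172, 160, 180, 158),
    waist = c(98, 88, 110, 95, 115, 99),
    sbp = c(122, 118, 138, 142, 131, 150),
    dbp = c(78, 75, 88, 90, 84, 95),
    glucose_0 = c(4.8, 5.0, 5.9, 6.2, 5.1, 7.4),
    glucose_30 = c(7.0, 7.2, 8.8, 9.1, 7.9, 12.0),
    glucose_120 = c(4.6, 5.2, 8.0, 7.9, 6.0, 11.5),
    insulin_0 = c(18, 22, 25, 20, 30, 28),
    insulin_30 = c(80, 95, 70, 60, 120, 90),
    insulin_120 = c(25, 30, 45, 50, 60, 80),
    cholesterol = c(4.9, 5.2, 6.3, 6.0, 5.8, 6.6),
    hdl = c(1.1, 1.4, 0.9, 1.2, 1.0, 1.1),
    ldl = c(3.0, 3.2, 4.1, 3.8, 3.6, 4.2),
    triglycerides = c(1.3, 1.5, 2.4, 1.9, 2.1, 2.6),
    hba1c = c(5.0, 5.1, 5.8, 5.9, 5.4, 6.6),
    crp = c(2.1, 3.4, 5.2, 4.4, 6.0, 7.5),
    pai1 = c(5.5, 6.0, 6.5, 5.8, 7.0, 6.2),
    homocysteine = c(10, 11, 13, 12.5, 11.8, 14),
    uric_acid = c(320, 290, 380, 340, 400, 360),
    alt = c(24, 20, 35, 28, 42, 30),
    ast = c(20, 19, 26, 22, 30, 24),
    ggt = c(22, 18, 35, 26, 48, 31),
    urea = c(4.1, 4.4, 5.0, 4.8, 4.6, 5.5),
    creatinine = c(80, 70, 90, 75, 95, 82),
    creatinine_clearance = c(130, 120, 105, 110, 125, 95),
    microalbuminuria = c(12, 18, 40, 25, 55, 70),
    on_lipid_therapy = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    on_antihypertensive_therapy = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    known_dm2 = rep(FALSE, 6),
    stringsAsFactors = FALSE
  )
}
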