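# Published reference values the acceptance tests compare against
# (frozen at the precision the study tables print).

DEL <- "Delivery to Client"
FRT <- "Freight Cost"

# linguistic weighting conversions: importance term, reliability term, TFN
printed_linguistic <- tibble::tribble(
  ~importance, ~reliability, ~l, ~m, ~u,
  "EI", "VW", 1, 1, 1, "EI", "W", 1, 1, 1, "EI", "M", 1, 1, 1,
  "EI", "H", 1, 1, 1, "EI", "VH", 1, 1, 1,
  "MOL", "VW", 0.19, 0.29, 0.43, "MOL", "W", 0.39, 0.59, 0.89,
  "MOL", "M", 0.49, 0.73, 1.10, "MOL", "H", 0.56, 0.85, 1.27,
  "MOL", "VH", 0.64, 0.96, 1.44,
  "LI", "VW", 0.12, 0.14, 0.19, "LI", "W", 0.24, 0.30, 0.39,
  "LI", "M", 0.29, 0.37, 0.49, "LI", "H", 0.34, 0.42, 0.56,
  "LI", "VH", 0.38, 0.48, 0.64,
  "VLI", "VW", 0.08, 0.10, 0.12, "VLI", "W", 0.17, 0.20, 0.24,
  "VLI", "M", 0.21, 0.24, 0.29, "VLI", "H", 0.24, 0.28, 0.34,
  "VLI", "VH", 0.27, 0.32, 0.38,
  "MUL", "VW", 0.06, 0.07, 0.08, "MUL", "W", 0.13, 0.15, 0.17,
  "MUL", "M", 0.16, 0.18, 0.21, "MUL", "H", 0.19, 0.21, 0.24,
  "MUL", "VH", 0.21, 0.24, 0.27)

# de-fuzzified input averages and criticality outputs per mode and objective
printed_averages <- local({
  v <- c(
    "F01", 2.637, 3.68, 2.973,   3.04, 2.802, 2.425,
    "F02", 1.86, 2.643, 2.214,   2.217, 2.625, 2.129,
    "F03", 3.6, 2.6, 3.099,      2.987, 3.825, 2.616,
    "F04", 7.067, 5.5, 4.792,    7.792, 4.752, 4.505,
    "F05", 3, 3.5, 3.247,        2.123, 3.2, 2.201,
    "F06", 3.6, 2.1, 2.913,      2.8, 3.375, 2.584,
    "F07", 1.65, 3.2, 2.135,     2.625, 2.123, 2.161,
    "F08", 4.25, 2.1, 2.83,      3.2, 3.6, 3.106,
    "F09", 2.275, 3, 2.463,      4.25, 3.413, 2.91,
    "F10", 2.8, 3.375, 3.119,    1.96, 2.8, 2.038,
    "F11", 2.275, 4.25, 2.953,   3.6, 2.1, 2.445,
    "F12", 1.65, 2.987, 2.111,   2.625, 2.123, 2.14,
    "F13", 6.25, 6.183, 5.597,   5.692, 5.306, 4.219,
    "F14", 8.097, 7.067, 6.696,  7.083, 5.875, 4.967,
    "F15", 2.8, 3.375, 2.698,    4, 2.773, 3.099,
    "F16", 5.953, 4.825, 4.95,   8.097, 6.183, 5.348,
    "F17", 3.2, 3.5, 3.425,      2.925, 2.4, 2.41,
    "F18", 2.45, 3.375, 2.913,   4, 2.773, 2.695,
    "F19", 1.797, 2.8, 2.188,    2.6, 1.96, 2.138,
    "F20", 5.25, 4.8, 4.688,     8.097, 5.417, 4.8,
    "F21", 3.15, 3.2, 3.272,     2.6, 3.15, 2.295)
  m <- matrix(v, ncol = 7, byrow = TRUE)
  tibble::tibble(
    mode_code = rep(m[, 1], each = 2),
    objective = rep(c(DEL, FRT), 21),
    s_avg = as.numeric(t(m[, c(2, 5)])),
    o_avg = as.numeric(t(m[, c(3, 6)])),
    inv_k = as.numeric(t(m[, c(4, 7)])))
})

# published RPN TFNs (the two cells inconsistent with the panel's own
# restriction products are kept exactly as printed)
printed_rpn <- local({
  v <- c(
    "F01", 24.00, 109.44, 264.00,    13.125, 62.40, 169.65,
    "F02", 27.00, 94.50, 222.75,     16.50, 78.40, 204.00,
    "F03", 28.50, 93.60, 224.40,     16.80, 66.15, 174.00,
    "F04", 48.75, 163.20, 342.00,    63.00, 184.45, 375.00,
    "F05", 35.00, 110.00, 250.25,    15.12, 64.512, 167.04,
    "F06", 30.00, 102.375, 240.00,   21.00, 75.60, 191.40,
    "F07", 16.875, 72.0, 185.625,    12.6, 56.0, 156.0,
    "F08", 17.5, 70.0, 178.75,       33.6, 103.95, 243.6,
    "F09", 15.0, 63.0, 165.0,        17.64, 67.20, 180.96,
    "F10", 33.75, 108.0, 247.5,      13.5, 57.60, 158.4,
    "F11", 35.0, 113.75, 260.0,      15.0, 63.0, 165.0,
    "F12", 16.8, 69.30, 182.7,       12.6, 56.0, 156.0,
    "F13", 99.0, 236.25, 459.0,      69.6, 187.20, 377.52,
    "F14", 170.625, 360.0, 617.5,    126.0, 286.875, 540.0,
    "F15", 15.0, 63.0, 165.0,        39.2, 115.5, 263.9,
    "F16", 86.4, 243.36, 432.0,      103.125, 252.0, 467.5,
    "F17", 44.1, 126.0, 282.75,      22.5, 81.0, 198.0,
    "F18", 30.0, 102.375, 240.0,     19.6, 73.5, 188.5,
    "F19", 18.0, 70.4, 184.8,        15.75, 64.0, 171.6,
    "F20", 86.625, 210.0, 413.44,    75.0, 204.75, 400.0,
    "F21", 37.8, 113.40, 261.0,      15.0, 63.0, 165.0)
  m <- matrix(v, ncol = 7, byrow = TRUE)
  tibble::tibble(
    mode_code = rep(m[, 1], each = 2),
    objective = rep(c(DEL, FRT), 21),
    rpn_l = as.numeric(t(m[, c(2, 5)])),
    rpn_m = as.numeric(t(m[, c(3, 6)])),
    rpn_u = as.numeric(t(m[, c(4, 7)])))
})

# published hybrid scores per objective and combined totals
printed_hybrid_q <- local({
  v <- c(
    "F01", 0.464874, 0.359503, "F02", 0.325713, 0.363592,
    "F03", 0.449661, 0.383703, "F04", 0.609799, 0.738464,
    "F05", 0.482154, 0.335996, "F06", 0.465203, 0.404119,
    "F07", 0.300962, 0.319882, "F08", 0.404198, 0.558455,
    "F09", 0.330843, 0.417422, "F10", 0.470117, 0.310128,
    "F11", 0.483008, 0.397655, "F12", 0.292733, 0.31173,
    "F13", 0.745367, 0.706748, "F14", 1, 0.8747,
    "F15", 0.347718, 0.52997, "F16", 0.726519, 0.959477,
    "F17", 0.518313, 0.385278, "F18", 0.449977, 0.408204,
    "F19", 0.292657, 0.338196, "F20", 0.675306, 0.699112,
    "F21", 0.489995, 0.329606)
  m <- matrix(v, ncol = 3, byrow = TRUE)
  tibble::tibble(
    mode_code = rep(m[, 1], each = 2),
    objective = rep(c(DEL, FRT), 21),
    q = as.numeric(t(m[, 2:3])))
})

printed_q_total <- c(
  F14 = 0.93735, F16 = 0.842998, F13 = 0.726058, F20 = 0.687209,
  F04 = 0.674131, F08 = 0.481326, F17 = 0.451796, F11 = 0.440331,
  F15 = 0.438844, F06 = 0.434661, F18 = 0.429091, F03 = 0.416682,
  F01 = 0.412189, F21 = 0.409801, F05 = 0.409075, F10 = 0.390123,
  F09 = 0.374132, F02 = 0.344653, F19 = 0.315426, F07 = 0.310422,
  F12 = 0.302231)
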