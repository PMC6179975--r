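# Canonical variable sets and the study parameterisation used as
# generator defaults: per-cluster means/SDs of the 19 retained quality
# variables, the panel-wide Pearson correlations among them, and the
# per-cluster sensory attribute profiles.

# Full 25-variable panel, in the conventional reporting order.
PANEL_VARS_25 <- c("GT", "AC", "PV", "TV", "BD", "FV", "SB", "LO", "PT",
                   "PTemp", "HRD", "ADH", "COH", "SPR", "Gmax", "GppGmax",
                   "TandGmax", "TempGel", "TempGmax", "Gtrough", "PC",
                   "S1", "S2", "S3", "S4")

# The six variables redundant at |r| > 0.75 with a retained partner.
PAPER_DROP_SET <- c("PTemp", "TempGel", "TV", "FV", "GppGmax", "TempGmax")

PANEL_VARS_19 <- setdiff(PANEL_VARS_25, PAPER_DROP_SET)

# The variables retained by forward-AIC selection in the reference
# analysis (LR-test reporting order).
MLR_SELECTED_VARS <- c("AC", "Gtrough", "BD", "S1", "TandGmax",
                       "S3", "GT", "COH", "Gmax", "S2")

#' Canonical variable sets of the quality panel
#'
#' @return A list with the full 25-variable set (`full`), the 19
#'   variables retained after correlation pruning (`retained`), the
#'   pinned redundant drop set (`dropped`), and the variables retained by
#'   forward-AIC selection in the reference analysis (`selected`).
#' @export
panel_variables <- function() {
  list(full = PANEL_VARS_25, retained = PANEL_VARS_19,
       dropped = PAPER_DROP_SET, selected = MLR_SELECTED_VARS)
}

#' Reference cluster archetypes for the quality panel
#'
#' Per-cluster means and standard deviations of the 19 retained quality
#' variables for the three cooking-quality ideotypes of the 211-accession
#' indica reference panel (cluster sizes 114, 70 and 27). Cluster 1 is
#' high-amylose / low-GT with high storage modulus; cluster 2 is
#' high-amylose / high-GT with low modulus; cluster 3 is
#' intermediate-amylose / high-GT with high breakdown and low setback.
#' These are the default parameterisation of [gen_feature_panel()].
#'
#' Units: GT degC; AC, PC percent; RVA parameters in instrument viscosity
#' units and minutes; HRD kg; ADH kg.s; COH, SPR, TandGmax ratios; Gmax,
#' Gtrough kPa; S1-S4 kPa/min (magnitudes).
#'
#' @return A list with elements `sizes` (length-3 integer), `means` and
#'   `sds` (19 x 3 matrices, variables x clusters), and `variables`.
#' @export
quality_archetypes <- function() {
  tab <- c(
    # var,   m1,    s1,    m2,    s2,    m3,    s3
    "GT",    74.81, 3.98,  77.10, 1.22,  77.94, 1.38,
    "AC",    25.07, 1.44,  25.51, 1.49,  21.22, 1.24,
    "PV",     2.23, 0.52,   2.28, 0.43,   2.49, 0.18,
    "BD",     0.67, 0.20,   0.78, 0.14,   1.10, 0.14,
    "SB",     0.69, 0.21,   0.61, 0.18,   0.15, 0.18,
    "LO",     1.36, 0.25,   1.39, 0.19,   1.24, 0.09,
    "PT",     5.96, 0.30,   5.84, 0.18,   5.89, 0.13,
    "HRD",    1.96, 0.50,   1.94, 0.50,   1.73, 0.47,
    "ADH",    0.02, 0.01,   0.02, 0.01,   0.04, 0.02,
    "COH",    0.44, 0.06,   0.42, 0.05,   0.43, 0.04,
    "SPR",    0.11, 0.02,   0.11, 0.01,   0.10, 0.01,
    "Gmax",  40.64, 9.62,  28.34, 7.20,  29.83, 7.26,
    "TandGmax", 0.11, 0.02, 0.12, 0.04,   0.11, 0.02,
    "Gtrough", 15.53, 4.31, 11.92, 2.33,  11.66, 1.83,
    "S1",     7.45, 2.66,   4.66, 1.88,   5.93, 2.49,
    "S2",     1.66, 0.58,   1.27, 0.33,   1.29, 0.22,
    "S3",     1.77, 0.70,   1.19, 0.58,   1.38, 0.63,
    "S4",     1.53, 0.81,   1.09, 0.63,   1.24, 0.71,
    "PC",     8.66, 1.26,   8.34, 1.02,   8.30, 1.00)
  m <- matrix(tab, ncol = 7, byrow = TRUE)
  vars <- m[, 1]
  num <- matrix(as.numeric(m[, -1]), ncol = 6)
  means <- num[, c(1, 3, 5)]
  sds <- num[, c(2, 4, 6)]
  dimnames(means) <- dimnames(sds) <- list(vars, paste0("cluster", 1:3))
  # reorder rows to the canonical retained-variable order
  means <- means[PANEL_VARS_19, ]
  sds <- sds[PANEL_VARS_19, ]
  list(sizes = c(114L, 70L, 27L), means = means, sds = sds,
       variables = PANEL_VARS_19)
}

# Panel-wide Pearson correlations among the 19 retained variables
# (lower triangle as a pair list).
cor_pairs_19 <- function() {
  txt <- "
AC GT -0.05
PV GT 0.08
PV AC -0.08
BD GT 0.54
BD AC -0.24
BD PV 0.48
SB GT -0.36
SB AC 0.34
SB PV 0.08
SB BD -0.61
LO GT 0.13
LO AC 0.17
LO PV 0.59
LO BD 0.29
LO SB 0.58
PT GT -0.37
PT AC -0.10
PT PV 0.48
PT BD -0.35
PT SB 0.32
PT LO 0.03
HRD GT -0.12
HRD AC 0.20
HRD PV -0.01
HRD BD -0.07
HRD SB 0.09
HRD LO 0.04
HRD PT -0.05
ADH GT 0.09
ADH AC -0.31
ADH PV -0.03
ADH BD 0.38
ADH SB -0.56
ADH LO -0.29
ADH PT -0.12
ADH HRD 0.22
COH GT 0.04
COH AC 0.15
COH PV 0.21
COH BD 0.14
COH SB 0.05
COH LO 0.20
COH PT -0.02
COH HRD 0.36
COH ADH -0.08
SPR GT -0.06
SPR AC 0.33
SPR PV -0.03
SPR BD -0.04
SPR SB 0.09
SPR LO 0.06
SPR PT -0.14
SPR HRD 0.54
SPR ADH -0.12
SPR COH 0.39
Gmax GT -0.34
Gmax AC 0.06
Gmax PV -0.17
Gmax BD -0.35
Gmax SB 0.28
Gmax LO -0.03
Gmax PT 0.11
Gmax HRD -0.12
Gmax ADH -0.15
Gmax COH -0.08
Gmax SPR 0.02
TandGmax GT 0.20
TandGmax AC 0.14
TandGmax PV -0.03
TandGmax BD 0.07
TandGmax SB -0.12
TandGmax LO -0.07
TandGmax PT -0.05
TandGmax HRD -0.01
TandGmax ADH 0.06
TandGmax COH -0.08
TandGmax SPR -0.07
TandGmax Gmax -0.12
Gtrough GT -0.26
Gtrough AC 0.08
Gtrough PV -0.10
Gtrough BD -0.34
Gtrough SB 0.29
Gtrough LO 0.00
Gtrough PT 0.16
Gtrough HRD -0.06
Gtrough ADH -0.14
Gtrough COH 0.05
Gtrough SPR 0.04
Gtrough Gmax 0.54
Gtrough TandGmax -0.04
PC GT -0.12
PC AC -0.37
PC PV -0.19
PC BD -0.41
PC SB 0.23
PC LO -0.14
PC PT 0.17
PC HRD -0.01
PC ADH -0.15
PC COH -0.14
PC SPR -0.14
PC Gmax 0.16
PC TandGmax -0.19
PC Gtrough 0.20
S1 GT -0.09
S1 AC -0.01
S1 PV -0.06
S1 BD -0.14
S1 SB 0.11
S1 LO -0.02
S1 PT 0.07
S1 HRD 0.07
S1 ADH -0.03
S1 COH 0.12
S1 SPR 0.03
S1 Gmax 0.39
S1 TandGmax -0.01
S1 Gtrough 0.18
S1 PC 0.04
S2 GT -0.12
S2 AC 0.03
S2 PV -0.06
S2 BD -0.20
S2 SB 0.18
S2 LO 0.02
S2 PT 0.06
S2 HRD 0.01
S2 ADH -0.12
S2 COH 0.05
S2 SPR -0.04
S2 Gmax 0.27
S2 TandGmax -0.03
S2 Gtrough 0.13
S2 PC 0.10
S2 S1 0.33
S3 GT 0.05
S3 AC 0.02
S3 PV -0.03
S3 BD -0.08
S3 SB 0.11
S3 LO 0.05
S3 PT -0.02
S3 HRD -0.04
S3 ADH -0.19
S3 COH 0.05
S3 SPR -0.02
S3 Gmax 0.33
S3 TandGmax 0.08
S3 Gtrough 0.25
S3 PC 0.06
S3 S1 0.39
S3 S2 0.34
S4 GT -0.06
S4 AC 0.01
S4 PV 0.01
S4 BD -0.11
S4 SB 0.07
S4 LO -0.03
S4 PT 0.13
S4 HRD 0.00
S4 ADH -0.02
S4 COH 0.11
S4 SPR -0.04
S4 Gmax 0.02
S4 TandGmax -0.10
S4 Gtrough 0.11
S4 PC 0.01
S4 S1 0.34
S4 S2 0.29
S4 S3 0.49
"
  read.table(text = txt, col.names = c("a", "b", "r"),
             stringsAsFactors = FALSE)
}

#' Default inter-variable correlation structure for the panel generator
#'
#' Builds the 19 x 19 correlation matrix among the retained quality
#' variables from the study's panel-wide Pearson correlations. If the
#' assembled matrix is not positive semi-definite it is repaired to the
#' nearest correlation matrix ([Matrix::nearPD()]); the maximum absolute
#' repair distance is attached as attribute `"psd_repair"`.
#'
#' @return A 19 x 19 correlation matrix with dimnames.
#' @export
default_panel_correlation <- function() {
  pp <- cor_pairs_19()
  v <- PANEL_VARS_19
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  for (i in seq_len(nrow(pp))) {
    R[pp$a[i], pp$b[i]] <- R[pp$b[i], pp$a[i]] <- pp$r[i]
  }
  repair_psd(R)
}

# Nearest-correlation-matrix repair, recording the distance moved.
repair_psd <- function(R, tol = 1e-8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= tol) {
    attr(R, "psd_repair") <- 0
    return(R)
  }
  Rp <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  dimnames(Rp) <- dimnames(R)
  d <- max(abs(Rp - R))
  rt_assert(d < 0.2, "non_psd",
            "correlation structure is too far from positive semi-definite")
  attr(Rp, "psd_repair") <- d
  Rp
}

#' Reference sensory attribute profiles per cluster
#'
#' Mean and standard deviation of each of the 13 descriptive texture
#' attributes (150-mm line scale) for the three quality clusters, over
#' the five profiled samples per cluster. Default parameterisation of
#' [gen_sensory_scores()].
#'
#' @return A list with `attributes`, `means` and `sds` (13 x 3 matrices)
#'   and `n_samples` (5 per cluster).
#' @export
sensory_archetypes <- function() {
  tab <- c(
    "initial starchy coating",   64.3, 11.9, 53.4,  4.8,  72.3,  6.4,
    "slickness",                 66.8, 14.5, 55.8,  8.3,  69.3, 13.3,
    "roughness",                 45.6,  7.1, 50.2, 12.7,  40.8,  7.5,
    "stickiness to the lips",    76.7, 16.1, 58.6, 14.2,  99.6,  3.5,
    "stickiness between grains", 76.6, 16.6, 55.4, 12.2,  82.5,  4.4,
    "springiness",               59.0,  7.7, 49.3,  7.6,  55.2,  4.2,
    "cohesiveness",              69.9,  8.4, 49.4, 10.2,  68.0,  7.3,
    "hardness",                  56.1,  4.7, 51.7,  6.3,  43.5,  8.3,
    "uniformity of bite",        93.3,  5.2, 65.9, 10.0,  91.6,  9.7,
    "cohesiveness of mass",      90.8,  4.1, 83.1, 12.8, 107.8,  5.8,
    "moisture absorption",       65.5, 13.1, 64.7,  6.3,  70.5,  7.6,
    "residual loose particles",  68.9,  5.4, 75.1,  8.9,  55.7, 11.1,
    "toothpack",                 71.5,  9.4, 51.2, 15.1,  66.4,  7.2)
  m <- matrix(tab, ncol = 7, byrow = TRUE)
  attrs <- m[, 1]
  num <- matrix(as.numeric(m[, -1]), ncol = 6)
  means <- num[, c(1, 3, 5)]
  sds <- num[, c(2, 4, 6)]
  dimnames(means) <- dimnames(sds) <- list(attrs, paste0("cluster", 1:3))
  list(attributes = attrs, means = means, sds = sds, n_samples = 5L)
}

SENSORY_ATTRIBUTES <- c(
  "initial starchy coating", "slickness", "roughness",
  "stickiness to the lips", "stickiness between grains", "springiness",
  "cohesiveness", "hardness", "uniformity of bite", "cohesiveness of mass",
  "moisture absorption", "residual loose particles", "toothpack")
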