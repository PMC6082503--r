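#' Synthetic cohort configuration
#'
#' Declares the study conditions the generator emulates: 606 subjects split
#' into 339 training, 173 validation and 94 blinded verification; 405
#' block-correlated signal features with a planted sparse linear relation
#' to the modified Gensini score; about 31% CAD prevalence; and per-subject
#' noise volumes that degrade feature quality.
#'
#' @param n_total,n_dev,n_train,n_val,n_verif Cohort sizes; must satisfy
#'   `n_train + n_val == n_dev` and `n_dev + n_verif == n_total`.
#' @param n_features Number of signal features (before the three appended
#'   demographics columns).
#' @param n_informative Features carrying the planted Gensini signal (one
#'   per correlation block, starting from the first block).
#' @param n_blocks Number of equicorrelated feature blocks.
#' @param within_block_corr Latent within-block correlation, in \[0, 1).
#' @param signal_strength Coefficient of the standardized Gensini score in
#'   the informative features.
#' @param prevalence_target Cohort CAD-positive fraction the angiogram
#'   generator is calibrated to.
#' @param noise_scale Multiplier linking noise volume to per-subject
#'   measurement noise: additive noise sd is scaled by
#'   `(1 + noise_volume * noise_scale)`.
#' @param seed Integer seed; the cohort is a pure function of
#'   (config, seed).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 606L, n_dev = 512L, n_train = 339L,
                          n_val = 173L, n_verif = 94L, n_features = 405L,
                          n_informative = 10L, n_blocks = 40L,
                          within_block_corr = 0.95, signal_strength = 1.0,
                          prevalence_target = 0.31, noise_scale = 0.2,
                          seed = 1L) {
  if (n_train + n_val != n_dev)
    stop("n_train + n_val must equal n_dev")
  if (n_dev + n_verif != n_total)
    stop("n_dev + n_verif must equal n_total")
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features")
  if (n_informative > n_blocks)
    stop("n_informative must not exceed n_blocks (one signal feature per block)")
  if (n_blocks > n_features) stop("n_blocks must not exceed n_features")
  if (within_block_corr < 0 || within_block_corr >= 1)
    stop("within_block_corr must lie in [0, 1)")
  if (prevalence_target < 0 || prevalence_target > 1)
    stop("prevalence_target must lie in [0, 1]")
  if (noise_scale < 0) stop("noise_scale must be nonnegative")
  structure(list(n_total = as.integer(n_total), n_dev = as.integer(n_dev),
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_verif = as.integer(n_verif),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_blocks = as.integer(n_blocks),
                 within_block_corr = within_block_corr,
                 signal_strength = signal_strength,
                 prevalence_target = prevalence_target,
                 noise_scale = noise_scale,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

# --- angiogram generator internals -----------------------------------------
# Lesion severity is a mixture of sub-critical (stenosis ~ U[20,65]) and
# critical (~ U[70,100]) lesions; FFR is measured with probability 0.5 for
# stenoses in [40,70) and declines with stenosis. All constants below are
# structural choices of the generator, calibrated analytically so that the
# cohort-level CAD-positive fraction matches prevalence_target.
.critical_frac <- 0.35
.extra_lesion_mean <- 1.5
.ffr_measure_prob <- 0.5
.collateral_prob <- 0.2
.ffr_mean <- function(stenosis) 0.95 - 0.004 * (stenosis - 40)
.ffr_sd <- 0.06

.segments <- c("LM", "pLAD", "mLAD", "dLAD", "pLCx", "OM", "RCA", "PDA",
               "OTHER")
.segment_probs <- c(0.02, 0.10, 0.13, 0.15, 0.08, 0.13, 0.25, 0.09, 0.05)

# P(sub-critical lesion is positive): FFR measured on [40,65] with prob 0.5
# and positive when below 0.80; stenosis ~ U[20,65].
.p_subcritical_positive <- function() {
  f <- function(s) .ffr_measure_prob *
    pnorm((0.80 - .ffr_mean(s)) / .ffr_sd)
  stats::integrate(f, 40, 65)$value / 45
}

# Solve the Bernoulli lesion rate from the target prevalence: a lesioned
# subject has 1 + Poisson(m) independent lesions, each positive w.p. pi, so
# P(positive | lesions) = 1 - (1 - pi) exp(-m pi).
.lesion_rate <- function(prevalence_target) {
  if (prevalence_target <= 0) return(0)
  pi_les <- .critical_frac + (1 - .critical_frac) * .p_subcritical_positive()
  p_pos <- 1 - (1 - pi_les) * exp(-.extra_lesion_mean * pi_les)
  min(1, prevalence_target / p_pos)
}

#' Simulate one angiographic record
#'
#' Lesion counts follow a zero-inflated count model (Bernoulli presence,
#' then 1 + Poisson extra lesions) whose presence rate is solved
#' analytically from `prevalence_target` so that the cohort CAD-positive
#' fraction (per [cad_label()]) matches the target. FFR is measured with
#' probability 0.5 for stenoses in \[40, 70) and declines with stenosis;
#' collaterals are present with probability 0.2 given any lesion >= 90%.
#'
#' @param config A [cohort_config()]; only `prevalence_target` is used.
#' @param p_lesion Optional override of the lesion presence rate.
#' @return An [angiogram_record()].
#' @export
simulate_angiogram <- function(config = cohort_config(), p_lesion = NULL) {
  if (is.null(p_lesion)) p_lesion <- .lesion_rate(config$prevalence_target)
  if (runif(1) >= p_lesion)
    return(angiogram_record())
  k <- 1L + rpois(1, .extra_lesion_mean)
  critical <- runif(k) < .critical_frac
  stenosis <- ifelse(critical, runif(k, 70, 100), runif(k, 20, 65))
  segment <- sample(.segments, k, replace = TRUE, prob = .segment_probs)
  ffr_measured <- stenosis >= 40 & stenosis < 70 &
    runif(k) < .ffr_measure_prob
  ffr <- rep(NA_real_, k)
  if (any(ffr_measured)) {
    s <- stenosis[ffr_measured]
    ffr[ffr_measured] <- pmin(1, pmax(0.2, rnorm(length(s), .ffr_mean(s),
                                                 .ffr_sd)))
  }
  collaterals <- any(stenosis >= 90) && runif(1) < .collateral_prob
  angiogram_record(stenosis, segment, ffr_measured, ffr, collaterals)
}

#' Assign stratified train/validation/verification splits
#'
#' Random assignment stratified by CAD label with exact split sizes from
#' the configuration (339/173/94 under the defaults): positives are
#' allocated proportionally across splits by largest remainder, negatives
#' fill the remaining slots.
#'
#' @param subjects Data frame with a `cad_label` column (0/1), exactly
#'   `n_total` rows.
#' @param config A [cohort_config()].
#' @return `subjects` with a `split` column
#'   (`"train"`/`"validation"`/`"verification"`).
#' @export
assign_splits <- function(subjects, config = cohort_config()) {
  n <- nrow(subjects)
  if (n != config$n_total)
    stop("expected ", config$n_total, " subjects, got ", n)
  sizes <- c(train = config$n_train, validation = config$n_val,
             verification = config$n_verif)
  pos <- which(subjects$cad_label == 1)
  neg <- which(subjects$cad_label != 1)
  # largest-remainder allocation of positives to the three splits
  q <- sizes * length(pos) / n
  base <- floor(q)
  extra <- length(pos) - sum(base)
  if (extra > 0) {
    up <- order(q - base, decreasing = TRUE)[seq_len(extra)]
    base[up] <- base[up] + 1
  }
  n_pos <- base
  n_neg <- sizes - n_pos
  if (any(n_neg < 0))
    stop("split sizes incompatible with the class balance")
  split <- character(n)
  pos <- sample(pos); neg <- sample(neg)
  split[pos] <- rep(names(sizes), times = n_pos)
  split[neg] <- rep(names(sizes), times = n_neg)
  subjects$split <- split
  subjects
}

#' Simulate the block-correlated feature matrix
#'
#' Features are arranged in `n_blocks` equicorrelated blocks built from a
#' shared latent factor per block (`sqrt(rho) g_block + sqrt(1-rho) e`),
#' guaranteeing within-block pairs above the reduction threshold. The first
#' feature of each of the first `n_informative` blocks additionally carries
#' `signal_strength` times the standardized modified Gensini score. The
#' idiosyncratic noise is additive measurement noise whose per-subject
#' standard deviation is proportional to `(1 + noise_volume * noise_scale)`
#' (normalised so the pooled within-block correlation equals
#' `within_block_corr`) -- noisier acquisitions yield strictly noisier
#' features.
#'
#' @param subjects Data frame with `gensini_modified` and `noise_volume`
#'   columns.
#' @param config A [cohort_config()].
#' @return Numeric matrix `n_total` x `n_features` with columns
#'   `f001`, `f002`, ...
#' @export
simulate_features <- function(subjects, config = cohort_config()) {
  n <- nrow(subjects)
  if (!all(c("gensini_modified", "noise_volume") %in% names(subjects)))
    stop("subjects must carry gensini_modified and noise_volume")
  p <- config$n_features
  nb <- config$n_blocks
  rho <- config$within_block_corr
  block_sizes <- rep(p %/% nb, nb)
  rem <- p - sum(block_sizes)
  if (rem > 0) block_sizes[seq_len(rem)] <- block_sizes[seq_len(rem)] + 1
  block_of <- rep(seq_len(nb), times = block_sizes)
  block_start <- c(1, cumsum(block_sizes)[-nb] + 1)

  g <- matrix(rnorm(n * nb), n, nb)             # latent block factors

  # Per-subject measurement-noise multiplier, proportional to
  # (1 + noise_volume * noise_scale) and normalised so its mean square over
  # the LogNormal(0, 0.5) noise-volume distribution is 1; the pooled
  # within-block correlation therefore equals within_block_corr while
  # noisier acquisitions still get strictly larger residual variance.
  a <- config$noise_scale
  norm2 <- 1 + 2 * a * exp(0.125) + a^2 * exp(0.5)
  noise_mult <- (1 + subjects$noise_volume * a) / sqrt(norm2)

  e <- matrix(rnorm(n * p), n, p) * noise_mult  # recycled down columns
  x <- sqrt(rho) * g[, block_of] + sqrt(1 - rho) * e

  z <- subjects$gensini_modified
  zsd <- sd(z)
  z <- if (zsd > 0) (z - mean(z)) / zsd else z * 0
  informative <- block_start[seq_len(config$n_informative)]
  if (length(informative))
    x[, informative] <- x[, informative] + config$signal_strength * z
  colnames(x) <- sprintf("f%03d", seq_len(p))
  attr(x, "informative") <- informative
  x
}

#' Generate a complete seeded synthetic cohort
#'
#' Draws demographics matched to the study's development-cohort moments
#' (age ~ N(61.5, 10.7) truncated to \[21, 95\], 60.2% male,
#' BMI ~ N(31.3, 7.0) truncated at 15, heart rate ~ N(72, 12) truncated to
#' \[40, 140\]), log-normal noise volumes (LogNormal(0, 0.5)), angiograms,
#' Gensini scores and CAD labels, stratified splits, and the feature
#' matrix with the three demographics columns (`age`, `sex_code`,
#' `heart_rate`) appended.
#'
#' @param config A [cohort_config()].
#' @param gensini A [gensini_config()].
#' @return An object of class `cad_cohort`: list with `subjects` (data
#'   frame), `lesions` (long data frame keyed by `subject_id`), `features`
#'   (matrix) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            gensini = gensini_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_total

  rtnorm <- function(n, mean, sd, lo, hi) {
    u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
    qnorm(u, mean, sd)
  }
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = rtnorm(n, 61.5, 10.7, 21, 95),
    sex = ifelse(runif(n) < 0.602, "male", "female"),
    heart_rate = rtnorm(n, 72, 12, 40, 140),
    bmi = rtnorm(n, 31.3, 7.0, 15, Inf),
    noise_volume = exp(rnorm(n, 0, 0.5)),
    stringsAsFactors = FALSE)

  p_lesion <- .lesion_rate(config$prevalence_target)
  angio <- lapply(seq_len(n), function(i)
    simulate_angiogram(config, p_lesion = p_lesion))

  les_list <- lapply(seq_len(n), function(i) {
    l <- angio[[i]]$lesions
    if (nrow(l)) cbind(subject_id = subjects$subject_id[i], l)
  })
  lesions <- do.call(rbind, les_list)
  if (is.null(lesions))
    lesions <- data.frame(subject_id = character(), stenosis = numeric(),
                          segment = character(), ffr_measured = logical(),
                          ffr = numeric())

  score <- lapply(angio, modified_gensini, config = gensini)
  subjects$collaterals <- vapply(angio, function(a) a$collaterals_present,
                                 logical(1))
  subjects$n_lesions <- vapply(angio, function(a) nrow(a$lesions),
                               integer(1))
  subjects$cad_label <- as.integer(vapply(score, function(s) s$cad_label,
                                          character(1)) == "positive")
  subjects$gensini_modified <- vapply(score, function(s) s$modified_score,
                                      numeric(1))

  subjects <- assign_splits(subjects, config)
  features <- simulate_features(subjects, config)
  features <- cbind(features,
                    age = subjects$age,
                    sex_code = as.numeric(subjects$sex == "male"),
                    heart_rate = subjects$heart_rate)
  rownames(features) <- subjects$subject_id

  structure(list(subjects = subjects, lesions = lesions,
                 features = features, config = config),
            class = "cad_cohort")
}

#' Extract one subject's angiogram record from a cohort
#'
#' @param cohort A `cad_cohort`.
#' @param subject_id Subject identifier.
#' @return An [angiogram_record()].
#' @export
cohort_angiogram <- function(cohort, subject_id) {
  row <- match(subject_id, cohort$subjects$subject_id)
  if (is.na(row)) stop("unknown subject_id: ", subject_id)
  l <- cohort$lesions[cohort$lesions$subject_id == subject_id, ,
                      drop = FALSE]
  angiogram_record(l$stenosis, l$segment, l$ffr_measured, l$ffr,
                   cohort$subjects$collaterals[row])
}

#' @export
print.cad_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Synthetic CAD cohort: %d subjects, %d features\n",
              nrow(s), ncol(x$features)))
  cat(sprintf("  splits: %s\n",
              paste(names(table(s$split)), table(s$split),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  CAD prevalence: %.1f%%; median noise volume %.2f\n",
              100 * mean(s$cad_label), stats::median(s$noise_volume)))
  invisible(x)
}
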