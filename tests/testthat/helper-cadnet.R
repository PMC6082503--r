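# Small cohort used by the fast end-to-end tests: same structure as the
# default study-sized configuration, scaled down.
small_config <- function(seed = 7L, ...) {
  defaults <- list(n_total = 220L, n_dev = 180L, n_train = 120L,
                   n_val = 60L, n_verif = 40L, n_features = 60L,
                   n_informative = 6L, n_blocks = 12L, seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# Per-split data list (x / gensini / label / noise) for GA-level tests.
split_data <- function(cohort, split) {
  idx <- cohort$subjects$split == split
  list(x = cohort$features[idx, , drop = FALSE],
       gensini = cohort$subjects$gensini_modified[idx],
       label = cohort$subjects$cad_label[idx],
       noise = cohort$subjects$noise_volume[idx])
}

# One-lesion angiogram shorthand.
lesion1 <- function(stenosis, segment = "pLAD", ffr = NA,
                    collaterals = FALSE) {
  angiogram_record(stenosis, segment, !is.na(ffr), ffr, collaterals)
}
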