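# Shared fixtures: all synthetic, built in code at test time.

# Default 13-subject plasma cohort restricted to the analysis window.
strong_plasma <- function(seed = 17) {
  subset_range(generate_cohort(preset("plasma_ibd", seed = seed)),
               c(1300, 1600))
}

# Minimal hand-built SpectraSet: `n` spectra on a small uniform grid.
tiny_set <- function(n = 4, wl = seq(1300, 1310, by = 0.5),
                     labels = rep(c("healthy", "UC"), length.out = n)) {
  a <- matrix(seq_len(n * length(wl)) / 10, nrow = n, byrow = TRUE)
  meta <- data.frame(
    id = paste0("s", seq_len(n), ":1"),
    subject_id = paste0("s", seq_len(n)),
    replicate = 1L, specimen = "plasma", label3 = labels,
    stringsAsFactors = FALSE)
  spectra_set(wl, a, meta)
}

# Confusion matrix with exact one-vs-rest counts for class "pos".
cm_from_counts <- function(TP, FP, TN, FN) {
  truth <- c(rep("pos", TP + FN), rep("neg", TN + FP))
  pred <- c(rep("pos", TP), rep("neg", FN), rep("neg", TN), rep("pos", FP))
  confusion_matrix(truth, pred)
}

snv_pipe <- function() preprocess_spec(list("snv"))
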