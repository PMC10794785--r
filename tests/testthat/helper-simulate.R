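# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, expr, envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# A mid-sized LCL-design study with known truth, reused by several files.
small_study <- function() {
  cached("small_study", {
    meta <- generate_design(lcl_design(), seed = 101)
    truth <- generate_truth(600, 0.18, 0.06, 0.04, seed = 102)
    counts <- generate_counts(meta, truth, library_size_mean = 3e5,
                              seed = 103)
    list(meta = meta, truth = truth, counts = counts,
         design = design_spec(c("x_count", "y_count"), "batch",
                              c("x_count", "y_count")))
  })
}

small_fit <- function() {
  cached("small_fit", {
    s <- small_study()
    fit_dosage_glm(s$counts, s$meta, s$design)
  })
}

# Replicated single-karyotype design for distributional checks.
replicate_meta <- function(n, karyotype = "46,XX") {
  generate_design(karyotype_design(karyotype, n, batches = "b1"), seed = 7)
}

# Brute-force hypergeometric upper tail by subset enumeration (oracle).
enumerate_overlap_p <- function(n_universe, n_a, n_b, k) {
  subsets <- combn(n_universe, n_b)
  hits <- colSums(subsets <= n_a)  # A is taken as elements 1..n_a
  mean(hits >= k)
}

# Closed-form Deming slope for variance ratio 1 (oracle).
closed_form_deming <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

# Independent transcription of the escape synthesis decision rules,
# written directly from the rule text (hand-built decision table).
expected_final_call <- function(n_escape, n_subject, avg_ar, hybrid) {
  n_inf <- n_escape + n_subject
  if (n_inf == 0) {
    if (is.na(hybrid)) return("no_call")
    return(if (hybrid >= 0.22) "escape" else "subject")
  }
  if (n_escape > n_inf / 2) return("escape")
  if (n_escape > 0 && (n_escape >= 2 || avg_ar >= 0.1)) return("escape")
  if (n_escape == 0) return("subject")
  if (n_subject > n_inf / 2 && avg_ar < 0.1) return("subject")
  "no_call"
}
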