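## Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

## reference synthetic blastocyst: 120 TE cells, D = 184 um, ICM 5500 um2,
## area CV 0.3, rendered as 12 noiseless views
ref_truth <- function() {
  if (is.null(.fixtures$truth)) {
    .fixtures$truth <- make_truth(120, 184, 5500, 0.3, seed = 7)
  }
  .fixtures$truth
}

ref_sequence <- function() {
  if (is.null(.fixtures$seq)) {
    .fixtures$seq <- render_sequence(ref_truth(), n_views = 12, seed = 3)
  }
  .fixtures$seq
}

ref_sphere <- function() ref_sequence()$spheres[[1]]

## Table-1-like synthetic cohort (226 blastocysts, 57.1% euploid)
ref_table <- function() {
  if (is.null(.fixtures$table)) {
    .fixtures$table <- simulate_feature_table(226, seed = 9)
  }
  .fixtures$table
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

## path where a user can drop the released 226-blastocyst table
supplementary_path <- function() {
  system.file("extdata", "supplementary_table5.csv", package = "blastometry")
}
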