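# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Extract the model matrix and outcome vector from a ppgr_design.
design_xy <- function(design, outcome, features = design$features) {
  stopifnot(inherits(design, "ppgr_design"))
  if (!outcome %in% names(design$data)) stop("unknown outcome: ", outcome)
  list(x = as.matrix(design$data[features]),
       y = design$data[[outcome]],
       patient_id = design$data$patient_id)
}

# Subset a design's rows, keeping metadata.
design_subset <- function(design, rows) {
  design$data <- design$data[rows, , drop = FALSE]
  design
}

r2_score <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}
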