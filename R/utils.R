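# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the user's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed derived from a master seed; keeps every
# derived seed a valid 32-bit integer.
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483629 + offset * 97003) %% 2147483629) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_cor_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && nrow(R) == ncol(R) &&
    max(abs(R - t(R))) < tol && max(abs(diag(R) - 1)) < tol
}

check_symmetric_pd <- function(M, name = "matrix", tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stopf("%s must be a square matrix", name)
  }
  if (max(abs(M - t(M))) > 1e-8) stopf("%s must be symmetric", name)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol) stopf("%s must be positive definite", name)
  invisible(ev)
}

# labels item_001, item_002, ...
item_labels <- function(n, prefix = "item") {
  sprintf("%s_%03d", prefix, seq_len(n))
}

default_dimension_names <- function(k) {
  nm <- c("anxious", "somatic", "sensitive", "sleep_related", "irritable",
          "vigilant", "sudomotor")
  if (k <= length(nm)) nm[seq_len(k)] else c(nm, paste0("dim_", seq(8, k)))[seq_len(k)]
}

default_severity_names <- function(m) {
  nm <- c("ISI", "MDD", "GAD", "SAD", "PD", "PTSD", "ASRS")
  if (m <= length(nm)) nm[seq_len(m)] else c(nm, paste0("sev_", seq(8, m)))[seq_len(m)]
}

# Convert a persons x items tibble/data.frame (optionally with person_id) to
# an integer matrix plus ids.
responses_to_matrix <- function(data) {
  df <- as.data.frame(data)
  pid <- NULL
  if ("person_id" %in% names(df)) {
    pid <- df$person_id
    df$person_id <- NULL
  }
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  if (is.null(pid)) pid <- seq_len(nrow(X))
  list(values = X, person_id = pid, item_ids = colnames(X))
}
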