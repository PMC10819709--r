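`%||%` <- function(a, b) if (is.null(a)) b else a

# One root seed per exported stochastic function; per-iteration work uses
# sub-seeds pre-drawn from the root so that adding iterations never perturbs
# earlier ones.
.substreams <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

.check_fraction <- function(x, name, open_zero = TRUE) {
  lo_ok <- if (open_zero) x > 0 else x >= 0
  if (length(x) != 1L || is.na(x) || !lo_ok || x > 1)
    stop("'", name, "' must be a fraction in ",
         if (open_zero) "(0, 1]" else "[0, 1]", call. = FALSE)
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop("'", name, "' must be an integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

.as_labels <- function(labels) {
  if (is(labels, "BinaryLabeling")) return(classLabels(labels))
  f <- factor(as.character(labels), levels = c("IBD", "PSC"))
  if (anyNA(f)) stop("labels must be 'PSC' or 'IBD'")
  f
}

# draw_X: correlation-side inputs may be a fixed matrix or a sampler
# function(seed) -> matrix (used for multiply-imputed platforms).
.draw_matrix <- function(x, seed) {
  if (is.function(x)) x(seed) else x
}

.new_proximity <- function(values, ids) {
  values <- (values + t(values)) / 2
  values[is.na(values)] <- 0
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  new("ProximityMatrix", values = values, sampleIds = as.character(ids))
}
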