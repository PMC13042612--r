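# Internal helpers shared across modules.

#' @importFrom stats rexp rpois rmultinom rbinom runif rnorm rgamma sd var
#'   cor.test t.test wilcox.test chisq.test fisher.test p.adjust pt qnorm
#'   setNames prcomp
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `code` under a fixed RNG seed without disturbing global RNG state.
# seed = NULL runs the code against the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# Derive a reproducible child seed from a base seed and a stage label,
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stop_ypg <- function(..., class = "ypopgen_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Great-circle distance in km between (lat, lon) points, haversine on a
# 6371-km sphere.  Inputs in decimal degrees; vectorised over rows.
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

# Significance star convention used throughout the reporting functions:
# * 0.01 <= p < 0.05, ** 0.001 <= p < 0.01, *** p < 0.001.
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05]  <- "*"
  out[!is.na(p) & p < 0.01]  <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
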