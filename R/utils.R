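# internal helpers shared across modules

#' Canonical predictor names in hatch -> larval -> settlement order
#'
#' The nine otolith-derived phenotypic and environmental variables used
#' throughout the pipeline, in their canonical life-stage order. This order
#' decides which column of a highly correlated pair is dropped and how
#' predictor-assignment ties are broken.
#'
#' @return Character vector of the nine predictor column names.
#' @export
predictor_names <- function() {
  c("hatch_date", "hatch_size", "moon_hatch",
    "pld", "grpld", "sst",
    "settlement_date", "settlement_size", "moon_settlement")
}

# most common value of an integer-coded vector, ties -> lowest code
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])  # which.max takes first = lowest code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# checksum of an in-memory object via its serialized temp file
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stopifnot_scalar_prob <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a single probability in [0,%s)", name,
                        if (open_right) "1" else "1]"), call. = FALSE)
  invisible(x)
}
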