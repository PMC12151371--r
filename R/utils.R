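#' @keywords internal
#' @importFrom stats predict coef
"_PACKAGE"

## Internal helpers shared across modules.

# Derive a stage-specific seed from a master seed deterministically.
# Keeps every derived seed inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(as.character(stage))) %% 99991L
  as.integer((as.integer(seed) %% 1000000L) * 2011L + offs) %% 2147483587L
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483587))
  expr
}

adhera_log <- function(..., verbose = getOption("adhera.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[adhera] ", ...)
}

#' Assert that two subject sets are disjoint (leakage guard)
#'
#' Every transform fitted inside the cross-validation pipeline is guarded by
#' this check: the subjects whose rows are used for fitting must not overlap
#' the held-out test subjects of the current fold.
#'
#' @param fit_subjects character vector of subject ids used to fit a transform
#'   or model.
#' @param test_subjects character vector of held-out subject ids.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; stops on overlap.
#' @export
assert_disjoint_subjects <- function(fit_subjects, test_subjects,
                                     what = "transform") {
  bad <- intersect(unique(fit_subjects), unique(test_subjects))
  if (length(bad) > 0L) {
    stop("leakage guard: ", what, " fitted on held-out subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Stable mode of a character/factor vector with explicit tie-break order.
modal_value <- function(x, order_pref) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- table(factor(x, levels = order_pref))
  names(tab)[which.max(tab)]  # which.max takes the first max -> order_pref
}
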