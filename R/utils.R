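#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Validation helpers: every user-facing constructor funnels through these so
## error messages always name the offending field.

abort_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_upper = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_field(field, "must be a whole number")
  }
  if (x < lower) abort_field(field, sprintf("must be >= %s", lower))
  if (strict_upper) {
    if (x >= upper) abort_field(field, sprintf("must be < %s", upper))
  } else if (x > upper) {
    abort_field(field, sprintf("must be <= %s", upper))
  }
  invisible(x)
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Workflow stages each receive their own RNG seed so that any stage can be
#' re-run in isolation and reproduce its output. The stage seed is the global
#' seed plus a small deterministic hash of the stage name, reduced modulo
#' 2^31 - 1 so it remains a valid R integer.
#'
#' @param global_seed Integer global seed for the run.
#' @param stage Character stage name (e.g. \code{"oplsda"}).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_stage_seed(1L, "oplsda")
derive_stage_seed <- function(global_seed, stage) {
  check_scalar_number(global_seed, "global_seed", integerish = TRUE)
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * (seq_along(codes) %% 97 + 1)) %% 1000003
  as.integer((abs(as.numeric(global_seed)) + h * 131) %% (2^31 - 1))
}

## Controlled vocabulary of metabolite classes used for SDM class summaries.
metabolite_class_vocabulary <- function() {
  c("amino acids", "bile acids", "FFA", "LPA", "LPC", "LPE", "MG",
    "nucleotides", "organic acid", "PA", "PC", "PE", "sugars", "other")
}
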