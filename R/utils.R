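#' @keywords internal
"_PACKAGE"

## Numerically stable log(sum(exp(lx))) for a vector of log-terms.
logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_arg("'%s' must be a single non-missing number", name)
  if (integer && x != floor(x))
    stop_arg("'%s' must be an integer, got %s", name, format(x))
  if (x < lower || x > upper)
    stop_arg("'%s' must be in [%s, %s], got %s", name,
             format(lower), format(upper), format(x))
  invisible(x)
}

## Accept a design as a two-column data.frame (sample_id, group) or as a
## named character vector sample_id -> group; return the named vector form.
as_design <- function(design) {
  if (is.data.frame(design)) {
    if (!all(c("sample_id", "group") %in% names(design)))
      stop_arg("design data.frame needs columns 'sample_id' and 'group'")
    out <- as.character(design$group)
    names(out) <- as.character(design$sample_id)
  } else if (is.character(design) && !is.null(names(design))) {
    out <- design
  } else {
    stop_arg("design must be a data.frame(sample_id, group) or a named character vector")
  }
  if (anyDuplicated(names(out)))
    stop_arg("duplicate sample ids in design")
  out
}
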