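#' @keywords internal
"_PACKAGE"

# Run `expr` under `set.seed(seed)` while leaving the caller's RNG state alone.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

#' Binary solution masks
#'
#' A solution mask is an integer vector of 0s and 1s over the candidate
#' feature set; bit `i` set means feature `i` is selected. These helpers
#' validate, format and compare masks.
#'
#' @param mask,a,b integer 0/1 vectors.
#' @param n mask length.
#' @return `as_mask()` a validated integer 0/1 vector; `mask_key()` a string
#'   key (the bits concatenated); `hamming()` the number of differing bits;
#'   `random_mask()` a uniform random nonzero mask of length `n`.
#' @examples
#' hamming(c(1, 0, 1), c(0, 0, 1))
#' mask_key(c(1, 0, 1, 1, 0))
#' @export
as_mask <- function(mask) {
  stop_if_not(length(mask) >= 1L && all(mask %in% c(0, 1)),
              "a solution mask must be a non-empty vector of 0s and 1s")
  as.integer(mask)
}

#' @rdname as_mask
#' @export
mask_key <- function(mask) paste(as.integer(mask), collapse = "")

#' @rdname as_mask
#' @export
hamming <- function(a, b) {
  stop_if_not(length(a) == length(b), "masks must have equal length")
  sum(as.integer(a) != as.integer(b))
}

#' @rdname as_mask
#' @export
random_mask <- function(n) {
  m <- sample(0:1, n, replace = TRUE)
  if (!any(m == 1L)) m[sample.int(n, 1L)] <- 1L
  as.integer(m)
}

# Ensure a mask selects at least one feature; if not, set one random bit.
repair_mask <- function(mask) {
  if (!any(mask == 1L)) mask[sample.int(length(mask), 1L)] <- 1L
  mask
}
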