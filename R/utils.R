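#' @importFrom rlang %||% .data abort warn enquo as_name
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n row_number across if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr imap list_rbind
NULL

# Derive a reproducible 32-bit child seed from a master seed and a stage key.
# Mixing is a small multiplicative hash over the key characters; all
# arithmetic stays below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  h <- as.double(seed) %% m
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

`%na%` <- function(x, y) ifelse(is.na(x), y, x)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Windows carry their construction parameters as attributes; recover them
# from the data when a tibble has passed through verbs that drop attributes.
window_size_of <- function(windows) {
  attr(windows, "window_size") %||% max(windows$end - windows$start)
}

window_step_of <- function(windows) {
  step <- attr(windows, "window_step")
  if (!is.null(step)) return(step)
  starts <- sort(unique(windows$start[windows$chrom == windows$chrom[1]]))
  if (length(starts) > 1) min(diff(starts)) else window_size_of(windows)
}

keep_window_attrs <- function(new, old) {
  attr(new, "window_size") <- attr(old, "window_size")
  attr(new, "window_step") <- attr(old, "window_step")
  new
}
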