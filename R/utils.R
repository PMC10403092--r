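#' @import data.table
#' @importFrom stats rbinom rnorm runif rlnorm rpois quantile median predict
#'   coef sd aggregate kmeans dist setNames complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## all timestamps in the package are integer minutes since PICU admission
MIN_PER_HOUR <- 60L
GRID_STEP <- 5L

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop_field(field, "must be a fraction in (0, 1)")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_field(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_field(field, "must be a non-negative number")
  as.numeric(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_field(field, "must be a positive number")
  as.numeric(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

## deterministic per-stage seed derivation; keeps results reproducible when a
## single global seed drives several stochastic stages
derive_seed <- function(seed, stage) {
  offsets <- c(generate = 11L, split = 23L, sample = 37L, glove = 41L,
               cnn = 43L, fit = 53L, cluster = 61L, boot = 71L,
               trajectories = 83L, null = 97L)
  off <- offsets[[stage]] %||% 101L
  as.integer((as.numeric(seed) * 1000003 + off * 7919) %% 2147483587)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
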