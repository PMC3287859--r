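# internal helpers shared across stages

#' Derive a stage-specific RNG seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed, the stage name, and (where relevant) a replicate
#' index, so stages are reproducible independently of execution order.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"genotypes"`, `"cv"`).
#' @param index Nonnegative integer, e.g. a replicate number. Default 0.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(42, "cv", 3)
stage_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  mod <- 2147483647 # 2^31 - 1, prime
  h <- (master %% mod)
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% mod
  h <- (h * 131 + (index %% mod)) %% mod
  as.integer(h %% (mod - 1L)) + 1L
}

# run expr with a local RNG state seeded by `seed` (NULL = use current state)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# center/scale columns to mean 0, 1/n-variance 1; errors on zero variance
std_columns <- function(m, what = "column") {
  n <- nrow(m)
  ctr <- colMeans(m)
  mc <- sweep(m, 2L, ctr, "-")
  scl <- sqrt(colMeans(mc^2))
  bad <- which(scl < 1e-12)
  if (length(bad) > 0L) {
    nm <- colnames(m)[bad] %||% as.character(bad)
    abort(paste0("zero-variance ", what, "(s): ",
                 paste(head(nm, 5L), collapse = ", "),
                 if (length(bad) > 5L) " ..." else ""))
  }
  list(x = sweep(mc, 2L, scl, "/"), center = ctr, scale = scl)
}

fmt_num <- function(x) formatC(x, digits = 6L, format = "g")
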