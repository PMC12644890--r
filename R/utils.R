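#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map2
NULL

# stop with a classed condition so tests can target specific failures
ms_abort <- function(msg, class) {
  abort(msg, class = paste0("microsucc_", class))
}

ms_warn <- function(msg, class) {
  warn(msg, class = paste0("microsucc_", class))
}

# all pipeline randomness funnels through here: one integer seed, one RNG kind
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  }
  force(code)
}

stage_levels <- function() c("managed", "recent", "late", "forest")

sir_substrates <- function() {
  c("glucose", "glycine", "oxalic_acid", "yeast", "lignin", "chitin")
}
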