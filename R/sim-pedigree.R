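#' Simulate a multi-generation pedigree
#'
#' Founders form generation 1; each later generation is produced by mating
#' randomly chosen sires and dams from any earlier generation (no selfing:
#' sire and dam are always distinct animals).  Offspring are split evenly
#' over the non-founder generations.  Animal ids are integers in birth
#' order, so parents always precede their offspring.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `id`, `sire`, `dam` (integer; `NA` =
#'   unknown parent), `sex` (`"M"`/`"F"`) and `generation`.
#' @export
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 6, n_generations = 3,
#'                                     n_animals = 20, seed = 4))
#' table(ped$generation)
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "pedigree"))
  nf <- config$n_founders
  ng <- config$n_generations
  n <- config$n_animals

  sex <- sample(c("M", "F"), n, replace = TRUE)
  # guarantee both sexes among founders so matings are always possible
  if (nf >= 2) {
    sex[1] <- "M"
    sex[2] <- "F"
  }
  id <- seq_len(n)
  sire <- rep(NA_integer_, n)
  dam <- rep(NA_integer_, n)
  generation <- rep(1L, n)

  n_off <- n - nf
  if (ng == 1L) {
    if (n_off > 0) {
      stop("n_generations = 1 but n_animals > n_founders: ",
           "no generation available for the extra animals", call. = FALSE)
    }
  } else if (n_off > 0) {
    per_gen <- diff(round(seq(0, n_off, length.out = ng)))
    idx <- nf
    for (g in seq(2, ng)) {
      earlier <- seq_len(idx)
      males <- earlier[sex[earlier] == "M"]
      females <- earlier[sex[earlier] == "F"]
      if (length(males) == 0 || length(females) == 0) {
        stop("impossible mating structure: an earlier generation lacks ",
             "one sex entirely", call. = FALSE)
      }
      k <- per_gen[g - 1]
      if (k == 0) next
      s <- sample(males, k, replace = TRUE)
      d <- sample(females, k, replace = TRUE)
      if (config$unknown_parent_prob > 0) {
        s[stats::runif(k) < config$unknown_parent_prob] <- NA_integer_
        d[stats::runif(k) < config$unknown_parent_prob] <- NA_integer_
      }
      rows <- idx + seq_len(k)
      sire[rows] <- s
      dam[rows] <- d
      generation[rows] <- g
      idx <- idx + k
    }
  }

  tibble::tibble(id = id, sire = sire, dam = dam,
                 sex = sex, generation = generation)
}
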