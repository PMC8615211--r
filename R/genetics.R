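GENOTYPE_STATES <- c("+/+", "+/-", "-/-")

# Gamete allele frequencies for one parental locus genotype.
gamete_freqs <- function(state) {
  switch(state,
         "+/+" = c("+" = 1, "-" = 0),
         "+/-" = c("+" = 0.5, "-" = 0.5),
         "-/-" = c("+" = 0, "-" = 1),
         stop("invalid genotype state: ", state))
}

# Offspring genotype distribution at one locus from two parental genotypes.
locus_offspring <- function(state1, state2) {
  g1 <- gamete_freqs(state1)
  g2 <- gamete_freqs(state2)
  p <- setNames(numeric(3), GENOTYPE_STATES)
  p["+/+"] <- g1["+"] * g2["+"]
  p["+/-"] <- g1["+"] * g2["-"] + g1["-"] * g2["+"]
  p["-/-"] <- g1["-"] * g2["-"]
  p
}

genotype_label <- function(states, loci) {
  paste(paste0(loci, ":", states), collapse = "; ")
}

#' Define a Mendelian segregation model with lethal genotype classes
#'
#' Supports one or two unlinked loci, selfing (one parent) or a cross (two
#' parents). Genotype states per locus are `+/+`, `+/-`, `-/-`. Lethal
#' genotype combinations are removed from the progeny distribution, which
#' is then renormalized over survivors.
#'
#' @param parent named character vector of per-locus genotypes, e.g.
#'   `c(mdar1 = "+/-", mdar4 = "-/-")`; names are locus labels.
#' @param parent2 optional second parent for a cross; defaults to `parent`
#'   (selfing).
#' @param lethal list of named character vectors describing lethal genotype
#'   combinations, e.g. `list(c(mdar1 = "-/-", mdar4 = "-/-"))`.
#' @return An object of class `segregation_model`.
#' @export
#' @examples
#' m <- segregation_model(c(mdar1 = "+/-", mdar4 = "-/-"),
#'                        lethal = list(c(mdar1 = "-/-", mdar4 = "-/-")))
#' expected_freqs(m)
segregation_model <- function(parent, parent2 = parent, lethal = list()) {
  loci <- names(parent)
  if (is.null(loci) || any(!nzchar(loci))) {
    stop("parent genotypes must be a named vector (names = locus labels)")
  }
  if (length(loci) < 1 || length(loci) > 2) {
    stop("only 1 or 2 unlinked loci are supported")
  }
  if (!identical(sort(names(parent2)), sort(loci))) {
    stop("both parents must cover the same loci")
  }
  for (s in c(parent, parent2)) {
    if (!s %in% GENOTYPE_STATES) stop("invalid genotype state: ", s)
  }
  for (l in lethal) {
    if (!all(names(l) %in% loci)) {
      stop("lethal genotype refers to unknown locus: ",
           paste(setdiff(names(l), loci), collapse = ", "))
    }
    for (s in l) {
      if (!s %in% GENOTYPE_STATES) stop("invalid genotype state: ", s)
    }
  }
  structure(list(parent = parent, parent2 = parent2[loci], lethal = lethal,
                 loci = loci),
            class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  cat("Segregation model (", length(x$loci), " unlinked loci)\n", sep = "")
  cat("  parent 1:", genotype_label(x$parent, x$loci), "\n")
  cat("  parent 2:", genotype_label(x$parent2, x$loci), "\n")
  if (length(x$lethal)) {
    for (l in x$lethal) {
      cat("  lethal:  ", genotype_label(l[x$loci[x$loci %in% names(l)]],
                                        x$loci[x$loci %in% names(l)]), "\n")
    }
  } else cat("  no lethal classes\n")
  invisible(x)
}

# Full progeny genotype distribution before lethality filtering.
progeny_distribution <- function(model) {
  loci <- model$loci
  per_locus <- lapply(loci, function(l) {
    locus_offspring(model$parent[[l]], model$parent2[[l]])
  })
  if (length(loci) == 1) {
    states <- data.frame(s1 = GENOTYPE_STATES, stringsAsFactors = FALSE)
    probs <- per_locus[[1]]
    labels <- paste0(loci[1], ":", GENOTYPE_STATES)
    states_list <- lapply(GENOTYPE_STATES, function(s) setNames(s, loci))
  } else {
    grid <- expand.grid(s1 = GENOTYPE_STATES, s2 = GENOTYPE_STATES,
                        stringsAsFactors = FALSE)
    probs <- per_locus[[1]][grid$s1] * per_locus[[2]][grid$s2]
    labels <- paste0(loci[1], ":", grid$s1, "; ", loci[2], ":", grid$s2)
    states_list <- lapply(seq_len(nrow(grid)), function(i) {
      setNames(c(grid$s1[i], grid$s2[i]), loci)
    })
  }
  list(labels = labels, probs = unname(probs), states = states_list)
}

is_lethal <- function(states, lethal) {
  for (l in lethal) {
    if (all(states[names(l)] == l)) return(TRUE)
  }
  FALSE
}

#' Expected progeny genotype frequencies
#'
#' Per-locus gamete frequencies are multiplied across loci (independence),
#' lethal genotype classes are zeroed, and the remainder is renormalized so
#' survivor probabilities sum to one. Genotypes with zero probability under
#' the cross are dropped from the output.
#'
#' @param model a [segregation_model()].
#' @param drop_zero drop genotypes with zero probability (default TRUE).
#' @return Named numeric vector of survivor genotype probabilities; names
#'   are `locus:state` combinations.
#' @export
expected_freqs <- function(model, drop_zero = TRUE) {
  if (!inherits(model, "segregation_model")) {
    stop("model must be a segregation_model")
  }
  dist <- progeny_distribution(model)
  lethal_mask <- vapply(dist$states, is_lethal, logical(1),
                        lethal = model$lethal)
  probs <- dist$probs
  probs[lethal_mask] <- 0
  total <- sum(probs)
  if (total <= 0) stop("all possible genotypes are lethal")
  probs <- probs / total
  out <- setNames(probs, dist$labels)
  if (drop_zero) out <- out[out > 0]
  out
}

#' Observed segregation ratio between two genotype classes
#'
#' The convention follows the printed form "ratio of A (n_a) to B (n_b)"
#' evaluated as `n_b / n_a`, reported to two decimals (61 and 78 seedlings
#' give 1.28).
#'
#' @param count_a count of the first genotype class (must be > 0).
#' @param count_b count of the second genotype class.
#' @return `count_b / count_a` rounded to 2 decimals.
#' @export
observed_ratio <- function(count_a, count_b) {
  if (count_a <= 0) stop("count_a must be positive")
  round(count_b / count_a, 2)
}

#' Chi-squared goodness of fit of observed counts to expected proportions
#'
#' @param observed_counts named (or positional) vector of counts.
#' @param expected_probs probabilities for the same categories, summing
#'   to 1.
#' @return List with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chisq_gof(c(61, 78), c(1 / 3, 2 / 3))
chisq_gof <- function(observed_counts, expected_probs) {
  if (length(observed_counts) != length(expected_probs)) {
    stop("observed and expected category sets differ in length")
  }
  if (!is.null(names(observed_counts)) && !is.null(names(expected_probs)) &&
      !identical(names(observed_counts), names(expected_probs))) {
    stop("observed and expected category names differ")
  }
  total <- sum(observed_counts)
  if (total < 1) stop("need at least one observation")
  if (abs(sum(expected_probs) - 1) > 1e-9) {
    stop("expected probabilities must sum to 1")
  }
  zero <- expected_probs == 0
  if (any(zero & observed_counts > 0)) {
    stop("expected probability 0 with nonzero observed count; ",
         "drop the category first")
  }
  e <- expected_probs * total
  keep <- !zero
  stat <- sum((observed_counts[keep] - e[keep])^2 / e[keep])
  df <- sum(keep) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
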