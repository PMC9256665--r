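#' Parameters for the Wright-Fisher forward simulation
#'
#' Bundles and validates the population-simulation parameters. Rescaling by
#' a factor \code{lambda_rescale} divides the population size and multiplies
#' the per-generation rates, leaving the population-scaled parameters
#' (4N\eqn{\mu}, 4Nr) unchanged; the simulator always works with the
#' rescaled (effective) values. The defaults correspond to a Drosophila-like
#' population of 10^6 individuals rescaled by 10^3: N = 1000 diploids,
#' per-site mutation rate 2.0e-5, recombination rate 2.8e-6, simulated for
#' 3000 generations, with 20 diploid individuals sampled at the end.
#'
#' @param N diploid population size (after rescaling).
#' @param L genome length in bp (a single linear sequence).
#' @param mu per-site per-generation mutation rate (pre-rescaling scale).
#' @param rec per-site per-generation recombination rate (pre-rescaling).
#' @param generations number of generations to simulate.
#' @param lambda_rescale rescaling factor applied as (N stays as given,
#'   mu*lambda, rec*lambda). Use 1 to pass effective rates directly.
#' @param n_sample number of diploid individuals sampled at the end.
#' @param seed integer random seed.
#' @return an object of class \code{sim_params}.
#' @examples
#' sim_params(N = 50, L = 1e4, mu = 1e-5, generations = 200, n_sample = 5)
#' @export
sim_params <- function(N = 1000L, L = 1e6, mu = 2e-5, rec = 2.8e-6,
                       generations = 3000L, lambda_rescale = 1,
                       n_sample = 20L, seed = 1L) {
  N <- as.integer(N); L <- as.integer(L)
  generations <- as.integer(generations)
  n_sample <- as.integer(n_sample)
  if (N < 1L) stopf("N must be >= 1")
  if (L < 1L) stopf("L must be >= 1")
  mu_eff <- mu * lambda_rescale
  rec_eff <- rec * lambda_rescale
  if (mu_eff < 0 || mu_eff > 1) stopf("rescaled mutation rate %g outside [0, 1]", mu_eff)
  if (rec_eff < 0 || rec_eff > 1) stopf("rescaled recombination rate %g outside [0, 1]", rec_eff)
  if (n_sample > N) stopf("n_sample (%d) exceeds N (%d)", n_sample, N)
  if (generations < 0L) stopf("generations must be >= 0")
  structure(list(N = N, L = L, mu = mu_eff, rec = rec_eff,
                 generations = generations, n_sample = n_sample,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Wright-Fisher simulation parameters\n")
  cat(sprintf("  N = %d diploids, L = %d bp, %d generations\n",
              x$N, x$L, x$generations))
  cat(sprintf("  mu = %g, rec = %g (effective per-site per-generation)\n",
              x$mu, x$rec))
  cat(sprintf("  theta = 4N*mu = %g per site; sample = %d diploids\n",
              4 * x$N * x$mu, x$n_sample))
  invisible(x)
}

#' Run a neutral Wright-Fisher forward simulation
#'
#' Simulates a constant-size diploid population forward in time from a
#' monomorphic ancestral sequence. Each generation, every offspring draws
#' two parents uniformly at random; each gamete is formed by recombining
#' the parent's two haplotypes with a Poisson(rec*L) number of crossovers
#' (breakpoints uniform) and receives Poisson(mu*L) new mutations at
#' uniform positions. Mutations follow an infinite-sites approximation:
#' a position that already carries a derived allele is resampled, so every
#' segregating site is biallelic with a single derived base (uniform over
#' the three alternatives). Sites fixed in the whole population are moved
#' to a `fixed` ledger and stripped from the per-haplotype sets.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param ancestral optional ancestral sequence as a character vector of
#'   bases of length \code{params$L}; generated from the seed if omitted.
#' @return an object of class \code{population_state}: list with
#'   \code{haps} (2N integer vectors of 0-based derived-allele positions,
#'   haplotypes 2i-1 and 2i belong to individual i), \code{fixed}
#'   (positions fixed since the start), \code{alt} (derived base per
#'   position, NA where none), \code{ancestral}, and \code{params}.
#' @export
run_wright_fisher <- function(params, ancestral = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  N <- params$N; L <- params$L
  if (is.null(ancestral)) ancestral <- random_sequence(L)
  if (length(ancestral) != L) stopf("ancestral sequence length != L")

  mu_g <- params$mu * L   # expected new mutations per gamete
  rec_g <- params$rec * L # expected crossovers per gamete

  haps <- rep(list(integer(0)), 2L * N)
  alt <- rep(NA_character_, L)
  has_alt <- logical(L)   # position ever mutated (segregating or fixed)
  fixed <- integer(0)
  n_g <- 2L * N

  for (gen in seq_len(params$generations)) {
    parent <- sample.int(N, n_g, replace = TRUE)
    strand <- sample.int(2L, n_g, replace = TRUE)  # which haplotype leads
    n_x <- if (rec_g > 0) stats::rpois(n_g, rec_g) else integer(n_g)
    # non-recombinant gametes copy one parental haplotype wholesale
    new_haps <- haps[2L * (parent - 1L) + strand]
    rec_idx <- which(n_x > 0L)
    for (g in rec_idx) {
      h1 <- haps[[2L * parent[g] - 2L + strand[g]]]
      h2 <- haps[[2L * parent[g] - 2L + (3L - strand[g])]]
      bp <- sort.int(sample.int(L, n_x[g]))  # 1-based breakpoints
      # segment parity: positions before bp[1] come from h1, etc.
      # haplotype sets are kept unsorted; findInterval only needs sorted bp
      keep1 <- findInterval(h1, bp) %% 2L == 0L
      keep2 <- findInterval(h2, bp) %% 2L == 1L
      new_haps[[g]] <- c(h1[keep1], h2[keep2])
    }
    # new mutations, infinite-sites: resample collisions with existing sites
    if (mu_g > 0) {
      n_m <- stats::rpois(n_g, mu_g)
      tot <- sum(n_m)
      if (tot > 0L) {
        pos <- integer(tot)
        need <- seq_len(tot)
        while (length(need) > 0L) {
          cand <- sample.int(L, length(need), replace = TRUE) - 1L
          ok <- !has_alt[cand + 1L] & !duplicated(cand)
          pos[need[ok]] <- cand[ok]
          need <- need[!ok]
        }
        alt[pos + 1L] <- random_alt_base(ancestral[pos + 1L])
        has_alt[pos + 1L] <- TRUE
        gam <- rep.int(seq_len(n_g), n_m)
        sp <- split(pos, gam)   # one append (one copy) per mutated gamete
        for (gname in names(sp)) {
          g <- as.integer(gname)
          new_haps[[g]] <- c(new_haps[[g]], sp[[gname]])
        }
      }
    }
    haps <- new_haps
    # periodic fixation/loss sweep keeps per-haplotype sets small
    if (gen %% 50L == 0L || gen == params$generations) {
      cnt <- tabulate(unlist(haps, use.names = FALSE) + 1L, nbins = L)
      fix_pos <- which(cnt == n_g) - 1L
      if (length(fix_pos) > 0L) {
        fixed <- c(fixed, fix_pos)
        haps <- lapply(haps, function(h) h[!(h %in% fix_pos)])
      }
      lost <- has_alt & cnt == 0L
      lost[fixed + 1L] <- FALSE
      if (any(lost)) {          # lost sites may mutate again later
        alt[lost] <- NA_character_
        has_alt[lost] <- FALSE
      }
    }
  }
  structure(list(haps = haps, fixed = sort.int(fixed), alt = alt,
                 ancestral = ancestral, params = params),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  seg <- length(unique(unlist(x$haps, use.names = FALSE)))
  cat(sprintf("Wright-Fisher population: %d diploids, L = %d bp\n",
              x$params$N, x$params$L))
  cat(sprintf("  %d segregating sites, %d fixed derived sites\n",
              seg, length(x$fixed)))
  invisible(x)
}

#' Sample diploid individuals from a simulated population
#'
#' Draws individuals uniformly without replacement, preserving haplotype
#' pairing. Population-fixed derived sites are re-attached to every sampled
#' haplotype so the sample's mutation sets are complete relative to the
#' ancestral sequence. \code{mode = "haploid"} instead draws one random
#' haplotype from each of \code{2*n_sample} distinct individuals and pairs
#' them into pseudo-diploids (the alternative reading of sampling 40
#' individuals' first alleles into 20 diploid genomes).
#'
#' @param state a \code{population_state}.
#' @param n_sample number of diploid individuals to form (default: value
#'   in the state's params).
#' @param seed optional seed for the sampling draw.
#' @param mode "diploid" (default) or "haploid" (see Details).
#' @return an object of class \code{population_sample}: list with
#'   \code{haps} (2*n_sample integer vectors, pair (2i-1, 2i) = individual
#'   i), \code{alt}, \code{ancestral}, \code{fixed}, \code{L}.
#' @export
sample_population <- function(state, n_sample = state$params$n_sample,
                              seed = NULL, mode = c("diploid", "haploid")) {
  stopifnot(inherits(state, "population_state"))
  mode <- match.arg(mode)
  n_sample <- as.integer(n_sample)
  N <- state$params$N
  if (!is.null(seed)) set.seed(seed)
  if (mode == "diploid") {
    if (n_sample > N) stopf("n_sample (%d) exceeds N (%d)", n_sample, N)
    ind <- sample.int(N, n_sample)
    idx <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  } else {
    if (2L * n_sample > N)
      stopf("haploid mode needs 2*n_sample (%d) <= N (%d)", 2L * n_sample, N)
    ind <- sample.int(N, 2L * n_sample)
    idx <- 2L * ind - 2L + sample.int(2L, 2L * n_sample, replace = TRUE)
  }
  haps <- state$haps[idx]
  if (length(state$fixed) > 0L)
    haps <- lapply(haps, function(h) c(h, state$fixed))
  structure(list(haps = haps, alt = state$alt, ancestral = state$ancestral,
                 fixed = state$fixed, L = state$params$L,
                 n_sample = n_sample),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  sites <- unique(unlist(x$haps, use.names = FALSE))
  cat(sprintf("Population sample: %d diploid individuals, %d sites carried\n",
              x$n_sample, length(sites)))
  invisible(x)
}

#' Derive the segregating-SNV truth set P from a population sample
#'
#' Produces one record per site carried by at least one sampled chromosome.
#' Sites carried by every chromosome (allele count = 2 * n_sample) are
#' retained and flagged \code{fixed}: they were introduced by the
#' population simulation but are monomorphic within the sample, so they
#' behave like divergence sites from a caller's point of view.
#'
#' @param sample a \code{population_sample}.
#' @return a \code{data.frame} of class \code{truth_p} with columns
#'   \code{pos} (0-based), \code{ref}, \code{alt}, \code{allele_count},
#'   \code{fixed}; attribute \code{dosage} holds the n_sites x n_individual
#'   genotype dosage matrix (0/1/2 copies of the derived allele).
#' @export
derive_truth_p <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  n <- sample$n_sample
  all_pos <- unlist(sample$haps, use.names = FALSE)
  pos <- sort.int(unique(all_pos))
  if (length(pos) == 0L) {
    out <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), allele_count = integer(0),
                      fixed = logical(0))
    attr(out, "dosage") <- matrix(0L, 0L, n)
    class(out) <- c("truth_p", "data.frame")
    return(out)
  }
  dosage <- matrix(0L, length(pos), n)
  for (i in seq_len(n)) {
    d1 <- tabulate(match(sample$haps[[2L * i - 1L]], pos), nbins = length(pos))
    d2 <- tabulate(match(sample$haps[[2L * i]], pos), nbins = length(pos))
    dosage[, i] <- d1 + d2
  }
  ac <- as.integer(rowSums(dosage))
  out <- data.frame(pos = pos,
                    ref = sample$ancestral[pos + 1L],
                    alt = sample$alt[pos + 1L],
                    allele_count = ac,
                    fixed = ac == 2L * n)
  attr(out, "dosage") <- dosage
  class(out) <- c("truth_p", "data.frame")
  out
}

#' Mean pairwise nucleotide diversity of a sample
#'
#' Average number of differences per site between two sampled chromosomes,
#' over all unordered pairs of the 2*n_sample haplotypes. At neutral
#' equilibrium its expectation is theta = 4*N*mu per site.
#'
#' @param sample a \code{population_sample}.
#' @return diversity per site (numeric scalar).
#' @export
pairwise_diversity <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  m <- 2L * sample$n_sample
  if (m < 2L) stopf("need at least 2 chromosomes")
  cnt <- tabulate(unlist(sample$haps, use.names = FALSE) + 1L, nbins = sample$L)
  k <- cnt[cnt > 0L]
  sum(k * (m - k)) / (m * (m - 1) / 2) / sample$L
}

#' Number of segregating sites in a sample
#'
#' Counts sites polymorphic within the sample (sample-fixed derived sites
#' excluded). The Watterson expectation is theta * a_{2n-1} * L where
#' a_m = sum(1/1..1/m).
#'
#' @param sample a \code{population_sample}.
#' @return integer count.
#' @export
segregating_sites <- function(sample) {
  m <- 2L * sample$n_sample
  cnt <- tabulate(unlist(sample$haps, use.names = FALSE) + 1L, nbins = sample$L)
  sum(cnt > 0L & cnt < m)
}
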