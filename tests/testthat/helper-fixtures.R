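# hand-built truth sets and independent oracles used across tests

make_truth_p <- function(pos, ref, alt, dosage) {
  dosage <- as.matrix(dosage)
  out <- data.frame(pos = as.integer(pos), ref = ref, alt = alt,
                    allele_count = as.integer(rowSums(dosage)),
                    fixed = rowSums(dosage) == 2L * ncol(dosage))
  attr(out, "dosage") <- dosage
  class(out) <- c("truth_p", "data.frame")
  out
}

make_truth_d <- function(pos, ancestral, ref_base, d_level = 0.01) {
  out <- data.frame(pos = as.integer(pos), ancestral = ancestral,
                    ref_base = ref_base,
                    d_level = rep_len(d_level, length(pos)))
  class(out) <- c("truth_d", "data.frame")
  out
}

make_calls <- function(pos, ref, alt, qual = 50,
                       QD = 20, FS = 1, MQ = 60, MQRankSum = 0,
                       ReadPosRankSum = 0, chrom = "chr1") {
  n <- length(pos)
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, qual = rep_len(qual, n),
                    QD = rep_len(QD, n), FS = rep_len(FS, n),
                    MQ = rep_len(MQ, n),
                    MQRankSum = rep_len(MQRankSum, n),
                    ReadPosRankSum = rep_len(ReadPosRankSum, n))
  class(out) <- c("vcf_calls", "data.frame")
  out
}

# a random polymorphic truth set with realistic het/hom dosages
random_truth_p <- function(n_sites, L, n_ind, seed) {
  set.seed(seed)
  pos <- sort(sample.int(L, n_sites)) - 1L
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  af <- runif(n_sites, 0.05, 0.6)
  dosage <- matrix(rbinom(n_sites * n_ind, 2, rep(af, n_ind)),
                   n_sites, n_ind)
  keep <- rowSums(dosage) > 0
  make_truth_p(pos[keep], ref[keep], unname(alt[keep]),
               dosage[keep, , drop = FALSE])
}

# brute-force per-call classification by scanning the truth lists
brute_force_classify <- function(calls, truth_p, truth_d) {
  vapply(seq_len(nrow(calls)), function(i) {
    p0 <- calls$pos[i] - 1L
    j <- which(truth_p$pos == p0)
    if (length(j) == 1L && calls$alt[i] == truth_p$alt[j]) return("TPP")
    k <- which(truth_d$pos == p0)
    if (length(k) == 1L && calls$alt[i] == truth_d$ancestral[k]) return("TPD")
    "FP"
  }, character(1))
}

# full hypergeometric enumeration of the two-sided Fisher p-value
fisher_enum_p <- function(a, b, c_, d_) {
  r1 <- a + b; r2 <- c_ + d_; c1 <- a + c_; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c_) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all permutations of seq_len(n) (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# exact two-sided permutation p-value for Spearman rho (no ties)
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rhos <- vapply(all_perms(n), function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# tiny deterministic repeat track on chr1
toy_track <- function() {
  repeat_track(data.frame(
    chrom = "chr1",
    start = c(100, 300, 500, 700, 900, 950),
    end = c(200, 400, 600, 800, 1000, 1000),
    class = c("LTR", "LINE", "DNA", "RC", "Simple_repeat", "LTR")))
}
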