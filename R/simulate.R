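# Synthetic-data generator: a genome carrying divergent copies of a
# proviral ENV-like segment flanked by (possibly mismatched) primer sites,
# and per-sample amplicon reads drawn from known locus proportions, with a
# case/control design and planted fold changes. Every emitted read carries
# its source locus in the read id for audit.

.DEFAULT_FWD <- "ACTGCCCAGGTRGGAGATGC" # synthetic ENV-like primers; one
.DEFAULT_REV <- "TCAGGCATGTTCACAGGCTC" # degenerate base exercises IUPAC

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a copy-specific ERV
#' amplicon study: ~27 divergent proviral copies, one dominant locus
#' (~48% of reads) over a long tail, 8 vs 8 case/control samples, and
#' IonTorrent-like reads (variable length, substitution plus
#' homopolymer-biased indel errors). `reads_per_sample` defaults to 5000
#' for fast exact-recovery experiments; the `full_depth` preset of
#' [sim_preset()] raises it to a production sequencing depth.
#'
#' @param seed Integer master seed (< 2^31).
#' @param n_loci Number of amplicon loci.
#' @param consensus_len Length of the shared core segment (bp), excluding
#'   primer footprints.
#' @param divergence Range of per-copy substitution divergence from the
#'   consensus core.
#' @param background_len Total background genome length (bp).
#' @param n_chrom Number of chromosomes the loci are spread over.
#' @param min_locus_gap Minimum background gap between neighbouring loci
#'   (bp). Keep it above the in-silico PCR `max_amplicon_len` so that
#'   neighbouring planted loci cannot pair into additional cross-locus
#'   amplicons during the scan.
#' @param primers A [primer_pair()].
#' @param primer_site_mismatches Candidate per-site mismatch counts
#'   (sampled uniformly per locus and primer, outside the protected 3'
#'   bases).
#' @param group_sizes Named vector `c(control = ..., case = ...)`.
#' @param dominant_mass,second_mass Baseline proportions of the two most
#'   expressed loci.
#' @param n_mid,mid_range Mid-tier loci count and log-uniform proportion
#'   range; the remaining loci form the tail.
#' @param tail_range Log-uniform proportion range of tail loci.
#' @param planted `data.frame(locus, fold)`: fold changes applied to the
#'   case group (locus as integer index or locus id).
#' @param planted_range Log-uniform baseline proportion range of planted
#'   loci (differentially expressed copies in such surveys sit among the
#'   rarer loci, at roughly 0.3-3% relative frequency).
#' @param reads_per_sample Mean reads per sample.
#' @param reads_dispersion NB dispersion of per-sample totals (0 = fixed).
#' @param read_len Read length range (nt), drawn uniformly.
#' @param sub_rate Per-base substitution error rate.
#' @param indel_rate Per-base indel error rate (homopolymer-biased).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_loci = 27L, consensus_len = 600L,
                       divergence = c(0.02, 0.08), background_len = 66000L,
                       n_chrom = 3L, min_locus_gap = 2001L,
                       primers = primer_pair(.DEFAULT_FWD, .DEFAULT_REV),
                       primer_site_mismatches = 0:2,
                       group_sizes = c(control = 8L, case = 8L),
                       dominant_mass = 0.48, second_mass = 0.075,
                       n_mid = 9L, mid_range = c(0.0166, 0.05),
                       tail_range = c(1e-4, 0.0166),
                       planted = data.frame(locus = integer(0),
                                            fold = numeric(0)),
                       planted_range = c(0.005, 0.03),
                       reads_per_sample = 5000L, reads_dispersion = 0,
                       read_len = c(140L, 180L),
                       sub_rate = 0.005, indel_rate = 0.001) {
  # YAML configs arrive with vectors as lists
  group_sizes <- unlist(group_sizes)
  divergence <- unlist(divergence)
  read_len <- unlist(read_len)
  if (is.list(planted)) planted <- as.data.frame(planted)
  stopifnot(seed == as.integer(seed), abs(seed) < 2^31 - 2,
            n_loci >= 1L, consensus_len > 0L,
            length(divergence) == 2L, divergence[1] <= divergence[2],
            all(c("control", "case") %in% names(group_sizes)),
            dominant_mass + second_mass < 1,
            n_mid + 2L <= n_loci || n_loci < 2L && n_mid == 0L,
            read_len[1] <= read_len[2],
            sub_rate >= 0, indel_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Named simulation presets
#'
#' `"full_depth"` raises reads per sample to a production amplicon
#' sequencing depth (mean ~70,694, overdispersed +/- ~24,812); `"clean"` switches all sequencing errors off so
#' every read is an exact amplicon substring; `"null"` is the default
#' no-effect design; `"planted"` plants a 4-fold increase and a 4-fold
#' decrease on two tail loci of the case group.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("null", "planted", "clean", "full_depth"),
                       ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(),
    planted = list(planted = data.frame(locus = c(15L, 20L),
                                        fold = c(4, 0.25))),
    clean = list(sub_rate = 0, indel_rate = 0),
    full_depth = list(reads_per_sample = 70694L,
                       reads_dispersion = (24812 / 70694)^2))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Concrete realization of an IUPAC string (each degenerate base resolved
# uniformly within its set).
.realize_iupac <- function(x) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  ch <- strsplit(toupper(x), "")[[1]]
  paste(vapply(ch, function(c) {
    s <- sets[[c]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

# Plant n mismatches into a realized primer site, never within the
# protected 3' bases and always incompatible with the primer's IUPAC set.
.mutate_site <- function(site, primer, n_mm, protect) {
  if (n_mm == 0L) return(site)
  ch <- strsplit(site, "")[[1]]
  pm <- .iupac_masks(primer)
  free <- which(seq_along(ch) <= length(ch) - protect & pm != 15L)
  pos <- sample(free, min(n_mm, length(free)))
  for (i in pos) {
    candidates <- names(.IUPAC_MASK)[1:4][bitwAnd(.IUPAC_MASK[1:4], pm[i]) == 0L]
    ch[i] <- sample(candidates, 1L)
  }
  paste(ch, collapse = "")
}

.mutate_substitutions <- function(seq, n) {
  if (n == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), min(n, length(ch)))
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Build a synthetic genome with planted amplicon loci
#'
#' Generates a consensus core segment, derives `n_loci` divergent copies,
#' flanks each with realized primer sites (optionally carrying mismatches
#' away from the protected 3' bases), and embeds them at random
#' non-overlapping positions (random strand) in random background sequence
#' split over `n_chrom` chromosomes. Baseline locus proportions and
#' planted case-group effects are recorded as ground truth. Deterministic
#' under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_genome`: list with `genome`
#'   (`DNAStringSet`), `loci` (truth table: `locus_id`, `chrom`, `start`,
#'   `end`, `strand`, `sequence`, `fwd_mismatches`, `rev_mismatches`,
#'   `prop_control`, `prop_case`), `planted`, and `config`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$primers
  nl <- config$n_loci

  consensus <- .random_dna(config$consensus_len)
  div <- runif(nl, config$divergence[1], config$divergence[2])

  amp <- character(nl)
  fwd_mm <- integer(nl)
  rev_mm <- integer(nl)
  for (i in seq_len(nl)) {
    core <- .mutate_substitutions(consensus,
                                  rbinom(1L, config$consensus_len, div[i]))
    fwd_mm[i] <- sample(config$primer_site_mismatches, 1L)
    rev_mm[i] <- sample(config$primer_site_mismatches, 1L)
    fsite <- .mutate_site(.realize_iupac(p$forward), p$forward, fwd_mm[i],
                          p$three_prime_protected)
    rsite <- .mutate_site(.realize_iupac(p$reverse), p$reverse, rev_mm[i],
                          p$three_prime_protected)
    amp[i] <- paste0(fsite, core, .revcomp_chr(rsite))
  }

  # distribute loci over chromosomes, then lay each chromosome out as
  # background gaps (>= min_locus_gap) interleaved with amplicons
  chrom_of <- sort(rep_len(seq_len(config$n_chrom), nl))
  chrom_len <- config$background_len %/% config$n_chrom
  chroms <- character(config$n_chrom)
  loci <- vector("list", nl)
  strands <- sample(c("+", "-"), nl, replace = TRUE)
  mingap <- config$min_locus_gap
  for (ci in seq_len(config$n_chrom)) {
    idx <- which(chrom_of == ci)
    m <- length(idx)
    free <- chrom_len - mingap * (m + 1L)
    if (free <= 0L)
      stop("background_len too small for n_loci at min_locus_gap = ", mingap)
    cuts <- sort(runif(m))
    gaps <- mingap + floor(diff(c(0, cuts, 1)) * free)
    pieces <- character(2L * m + 1L)
    pieces[1L] <- .random_dna(gaps[1L])
    pos <- gaps[1L]
    for (j in seq_len(m)) {
      a <- amp[idx[j]]
      ins <- if (strands[idx[j]] == "+") a else .revcomp_chr(a)
      pieces[2L * j] <- ins
      loci[[idx[j]]] <- data.frame(
        chrom = paste0("chr", ci), start = as.integer(pos),
        end = as.integer(pos + nchar(a)),
        strand = strands[idx[j]], sequence = a,
        fwd_mismatches = fwd_mm[idx[j]], rev_mismatches = rev_mm[idx[j]])
      pos <- pos + nchar(a)
      pieces[2L * j + 1L] <- .random_dna(gaps[j + 1L])
      pos <- pos + gaps[j + 1L]
    }
    chroms[ci] <- paste(pieces, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(chroms)
  names(genome) <- paste0("chr", seq_len(config$n_chrom))

  truth <- do.call(rbind, loci)
  ord <- order(match(truth$chrom, names(genome)), truth$start)
  truth <- truth[ord, , drop = FALSE]
  krank <- stats::ave(seq_len(nrow(truth)), truth$chrom, FUN = seq_along)
  truth <- cbind(locus_id = sprintf("%s-%d", truth$chrom, krank), truth)
  rownames(truth) <- NULL

  planted <- config$planted
  if (nrow(planted) > 0L && !is.numeric(planted$locus))
    planted$locus <- match(planted$locus, truth$locus_id)

  # baseline proportions: dominant + second + mid tier + tail; planted
  # effects are placed on rarer loci (the altered copies a copy-specific
  # survey is after sit well below the dominant copy)
  n_free <- nl - nrow(planted)
  stopifnot(n_free >= 0L)
  roles <- character(nl)
  roles[planted$locus] <- "planted"
  pool <- setdiff(seq_len(nl), planted$locus)
  pool_roles <- rep(c("dominant", "second", "mid", "tail"),
                    c(1L, 1L, config$n_mid, max(0L, n_free - 2L -
                                                  config$n_mid)))
  roles[pool] <- sample(pool_roles)[seq_along(pool)]
  lu <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))
  prop <- numeric(nl)
  prop[roles == "dominant"] <- config$dominant_mass
  prop[roles == "second"] <- config$second_mass
  prop[roles == "mid"] <- lu(sum(roles == "mid"), config$mid_range)
  prop[roles == "tail"] <- lu(sum(roles == "tail"), config$tail_range)
  prop[roles == "planted"] <- lu(sum(roles == "planted"),
                                 config$planted_range)
  prop <- prop / sum(prop)
  truth$prop_control <- prop

  case <- prop
  if (nrow(planted) > 0L)
    case[planted$locus] <- case[planted$locus] * planted$fold
  truth$prop_case <- case / sum(case)
  if (nrow(planted) > 0L) planted$locus_id <- truth$locus_id[planted$locus]

  structure(list(genome = genome, loci = truth, planted = planted,
                 config = config),
            class = "sim_genome")
}

# Inject substitution and homopolymer-biased indel errors into one read.
.sequencing_errors <- function(seq, sub_rate, indel_rate) {
  n <- nchar(seq)
  nsub <- rbinom(1L, n, sub_rate)
  if (nsub > 0L) seq <- .mutate_substitutions(seq, nsub)
  nind <- rbinom(1L, n, indel_rate)
  if (nind > 0L) {
    ch <- strsplit(seq, "")[[1]]
    # weight positions inside homopolymer runs 4x
    w <- c(1, ifelse(ch[-1] == ch[-length(ch)], 4, 1))
    pos <- sample(length(ch), min(nind, length(ch)), prob = w)
    for (i in sort(pos, decreasing = TRUE)) {
      if (runif(1) < 0.5) ch <- ch[-i]                       # deletion
      else ch <- append(ch, ch[i], after = i)                # duplication
    }
    seq <- paste(ch, collapse = "")
  }
  seq
}

#' Simulate per-sample amplicon reads from a synthetic genome
#'
#' For each sample, source loci are drawn multinomially from the group's
#' true proportions; each read is a prefix of the amplicon sequence from
#' one of its two ends (unstranded protocol), with a uniform length draw
#' and simulated substitution/indel errors. Read ids encode
#' `sample|locus|index` so every read can be audited against the truth.
#' Deterministic under `config$seed` (an internal offset separates the
#' read-level stream from the genome build).
#'
#' @param sim A `sim_genome` from [build_genome()].
#' @return List with `reads` (one table: `sample`, `read_id`, `sequence`,
#'   `quality`), `truth_counts` (loci x samples emitted-read counts),
#'   `samples` (`sample`, `group`), and `sim`.
#' @export
simulate_reads <- function(sim) {
  stopifnot(inherits(sim, "sim_genome"))
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  samp <- sprintf("%s_%d", groups,
                  unlist(lapply(cfg$group_sizes, seq_len), use.names = FALSE))
  nl <- nrow(sim$loci)
  truth_counts <- matrix(0L, nl, length(samp),
                         dimnames = list(sim$loci$locus_id, samp))
  out <- vector("list", length(samp))
  for (si in seq_along(samp)) {
    prop <- if (groups[si] == "case") sim$loci$prop_case
            else sim$loci$prop_control
    n <- cfg$reads_per_sample
    if (cfg$reads_dispersion > 0)
      n <- rnbinom(1L, mu = n, size = 1 / cfg$reads_dispersion)
    cnt <- as.integer(rmultinom(1L, n, prop))
    truth_counts[, si] <- cnt
    src <- rep.int(seq_len(nl), cnt)
    nn <- length(src)
    lens <- sample(seq.int(cfg$read_len[1], cfg$read_len[2]), nn,
                   replace = TRUE)
    from_rev <- runif(nn) < 0.5
    ampl <- sim$loci$sequence
    alen <- nchar(ampl)
    L <- pmin(lens, alen[src])
    seqs <- substr(ampl[src], 1L, L)
    if (any(from_rev)) {
      i <- which(from_rev)
      seqs[i] <- .revcomp_chr(substr(ampl[src[i]], alen[src[i]] - L[i] + 1L,
                                     alen[src[i]]))
    }
    if (cfg$sub_rate > 0 || cfg$indel_rate > 0) {
      nsub <- rbinom(nn, L, cfg$sub_rate)
      nind <- rbinom(nn, L, cfg$indel_rate)
      for (j in which(nsub > 0L & nind == 0L))
        seqs[j] <- .mutate_substitutions(seqs[j], nsub[j])
      for (j in which(nind > 0L))
        seqs[j] <- .sequencing_errors(seqs[j], cfg$sub_rate, cfg$indel_rate)
    }
    out[[si]] <- data.frame(
      sample = samp[si],
      read_id = sprintf("%s|%s|r%06d", samp[si],
                        sim$loci$locus_id[src], seq_len(nn)),
      sequence = seqs, quality = strrep("I", nchar(seqs)),
      row.names = NULL)
  }
  list(reads = do.call(rbind, out), truth_counts = truth_counts,
       samples = data.frame(sample = samp, group = groups, row.names = NULL),
       sim = sim)
}
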