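#' Configuration for a synthetic ceRNA scenario
#'
#' Defines a two-condition (laying vs broody style) negative-binomial
#' count experiment over the four RNA classes, with planted differential
#' expression and planted ceRNA triplets. A planted triplet couples one
#' miRNA, one ceRNA (lncRNA or circRNA, alternating while the circRNA pool
#' lasts) and one mRNA: the miRNA is differentially expressed, both
#' targets' means are modulated by `exp(-coupling_strength * z)` where `z`
#' is the miRNA's standardized log-scale signal, and both target sequences
#' carry an 8mer seed site for the miRNA.
#'
#' @param n_replicates_per_group samples per condition (>= 2; default 3,
#'   mirroring the 3-vs-3 ovary design).
#' @param n_mirna,n_mrna,n_lncrna,n_circrna feature counts per class.
#' @param n_planted_triplets number of planted ceRNA triplets
#'   (<= min(n_lncrna, n_mrna)).
#' @param n_planted_de_per_class extra (non-triplet) DE features planted
#'   in each class, alternating up/down.
#' @param base_mean expected counts of planted features (decoys draw
#'   log-normal means around it).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param coupling_strength log-scale repression slope of the miRNA on its
#'   targets (>= 0; 0 decouples them).
#' @param de_log2fc planted log2 fold change, condition B vs A (>= 0; 0
#'   plants no differential expression).
#' @param seed integer RNG seed; a fixed seed makes the scenario
#'   bit-identical across calls.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_replicates_per_group = 3,
                            n_mirna = 20, n_mrna = 100, n_lncrna = 60,
                            n_circrna = 30, n_planted_triplets = 10,
                            n_planted_de_per_class = 10,
                            base_mean = 200, nb_dispersion = 0.1,
                            coupling_strength = 1.0, de_log2fc = 2.0,
                            seed = 1L) {
  cfg <- list(
    n_replicates_per_group = assert_count(n_replicates_per_group,
                                          "n_replicates_per_group", 2L),
    n_mirna = assert_count(n_mirna, "n_mirna", 1L),
    n_mrna = assert_count(n_mrna, "n_mrna", 1L),
    n_lncrna = assert_count(n_lncrna, "n_lncrna", 1L),
    n_circrna = assert_count(n_circrna, "n_circrna", 1L),
    n_planted_triplets = assert_count(n_planted_triplets,
                                      "n_planted_triplets", 0L),
    n_planted_de_per_class = assert_count(n_planted_de_per_class,
                                          "n_planted_de_per_class", 0L),
    base_mean = assert_scalar_number(base_mean, "base_mean", 0, strict = TRUE),
    nb_dispersion = assert_scalar_number(nb_dispersion, "nb_dispersion", 0,
                                         strict = TRUE),
    coupling_strength = assert_scalar_number(coupling_strength,
                                             "coupling_strength", 0),
    de_log2fc = assert_scalar_number(de_log2fc, "de_log2fc", 0),
    seed = assert_count(seed, "seed")
  )
  if (cfg$n_planted_triplets > min(cfg$n_lncrna, cfg$n_mrna)) {
    stop("n_planted_triplets must not exceed min(n_lncrna, n_mrna)")
  }
  structure(cfg, class = "scenario_config")
}

# within-group biological spread of a planted miRNA's log2 signal; fixed so
# that the group effect (de_log2fc) dominates while correlations remain
# estimable within groups
LATENT_NOISE_SD <- 0.25
TARGET_SEQ_LEN <- 300L
MIRNA_SEQ_LEN <- 22L

#' Generate a self-contained synthetic scenario
#'
#' Draws counts, transcript sequences, transcript models and the ground
#' truth for one scenario. Counts are negative binomial with per-sample
#' log-normal(0, 0.1) library-size factors per class. Planted miRNAs carry
#' a +/- `de_log2fc` group shift (alternating direction); their targets'
#' means are multiplied by `exp(-coupling_strength * z)` with `z` the
#' standardized miRNA log signal, giving negative miRNA-target and
#' positive ceRNA-mRNA correlation in expectation. Planted target
#' sequences contain an 8mer seed site for their miRNA; decoy sequences
#' are screened to contain no seed core of any planted miRNA. Transcript
#' models place lncRNAs into all five positional classes round-robin.
#'
#' @param config a [scenario_config()].
#' @return Object of class `cerna_scenario`: list with `config`, `counts`
#'   (named list of [count_matrix()] per class), `condition` (named
#'   factor), `sequences` (named character, DNA on disk conventions),
#'   `transcripts` (list of [transcript_model()]), `lnc_design` (designed
#'   positional class per lncRNA) and `truth` (list `planted_de`,
#'   `planted_triplets`, `planted_target_pairs` as data.frames).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_replicates_per_group
  samples <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  condition <- stats::setNames(
    factor(rep(c("groupA", "groupB"), each = n)), samples)
  group_b <- rep(c(0, 1), each = n)

  ids <- list(
    miRNA = sprintf("miR-%03d", seq_len(config$n_mirna)),
    mRNA = sprintf("gene-%03d", seq_len(config$n_mrna)),
    lncRNA = sprintf("lnc-%03d", seq_len(config$n_lncrna)),
    circRNA = sprintf("circ-%03d", seq_len(config$n_circrna))
  )

  plan <- plan_triplets(config)
  t_n <- nrow(plan)

  # latent log2 signal per distinct planted miRNA (reused across triplets
  # that recycle a miRNA)
  mir_idx <- unique(plan$mirna)
  latent <- list(); zscore <- list(); mir_dir <- integer(0)
  for (j in seq_along(mir_idx)) {
    # paired alternation (+ + - - ...): keeps planted directions balanced
    # within each ceRNA class even though classes alternate per triplet
    d <- if (((j - 1L) %/% 2L) %% 2L == 0L) 1L else -1L
    a <- d * config$de_log2fc * group_b +
      stats::rnorm(2 * n, 0, LATENT_NOISE_SD)
    key <- as.character(mir_idx[j])
    latent[[key]] <- a
    zscore[[key]] <- if (stats::sd(a) > 0) (a - mean(a)) / stats::sd(a) else
      a * 0
    mir_dir[key] <- d
  }

  # per-class library size factors
  sf <- lapply(ids, function(x) stats::rlnorm(2 * n, 0, 0.1))

  size <- 1 / config$nb_dispersion
  draw_counts <- function(mu) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = size),
           nrow = nrow(mu), dimnames = dimnames(mu))
  }

  # build the per-feature mean matrix for one class
  planted_rows <- list()
  class_mu <- function(class) {
    nf <- length(ids[[class]])
    mu <- matrix(0, nf, 2 * n, dimnames = list(ids[[class]], samples))
    planted <- rep(FALSE, nf)

    if (class == "miRNA") {
      for (key in names(latent)) {
        i <- as.integer(key)
        mu[i, ] <- config$base_mean * 2^latent[[key]]
        planted[i] <- TRUE
        if (config$de_log2fc > 0) {
          planted_rows[[length(planted_rows) + 1L]] <<- data.frame(
            feature_id = ids$miRNA[i], class = "miRNA",
            direction = if (mir_dir[key] > 0) "up" else "down")
        }
      }
    } else {
      col <- switch(class, mRNA = "mrna", lncRNA = "lnc", circRNA = "circ")
      sel <- plan[!is.na(plan[[col]]), , drop = FALSE]
      for (r in seq_len(nrow(sel))) {
        i <- sel[[col]][r]
        key <- as.character(sel$mirna[r])
        mu[i, ] <- config$base_mean *
          exp(-config$coupling_strength * zscore[[key]])
        planted[i] <- TRUE
        if (config$de_log2fc > 0 && config$coupling_strength > 0) {
          planted_rows[[length(planted_rows) + 1L]] <<- data.frame(
            feature_id = ids[[class]][i], class = class,
            direction = if (mir_dir[key] > 0) "down" else "up")
        }
      }
    }

    # extra planted DE decoys, alternating direction
    free <- which(!planted)
    n_extra <- min(config$n_planted_de_per_class, length(free))
    for (k in seq_len(n_extra)) {
      i <- free[k]
      d <- if (k %% 2L == 1L) 1L else -1L
      mu[i, ] <- config$base_mean * 2^(d * config$de_log2fc * group_b)
      planted[i] <- TRUE
      if (config$de_log2fc > 0) {
        planted_rows[[length(planted_rows) + 1L]] <<- data.frame(
          feature_id = ids[[class]][i], class = class,
          direction = if (d > 0) "up" else "down")
      }
    }

    # decoys: flat, feature-specific means
    for (i in which(!planted)) {
      mu[i, ] <- stats::rlnorm(1, log(config$base_mean), 0.5)
    }
    sweep(mu, 2L, sf[[class]], "*")
  }

  counts <- list()
  for (class in RNA_CLASSES) {
    counts[[class]] <- count_matrix(draw_counts(class_mu(class)),
                                    class, condition)
  }

  truth <- build_truth(plan, ids, planted_rows)
  sequences <- generate_sequences(config, ids, plan, truth)
  tx <- generate_transcripts(ids)

  structure(list(config = config, counts = counts, condition = condition,
                 sequences = sequences, transcripts = tx$models,
                 lnc_design = tx$lnc_design, truth = truth),
            class = "cerna_scenario")
}

#' @export
print.cerna_scenario <- function(x, ...) {
  cat(sprintf(paste0("<cerna_scenario> seed %d: %d+%d samples; ",
                     "%d miRNA / %d mRNA / %d lncRNA / %d circRNA; ",
                     "%d planted triplet(s)\n"),
              x$config$seed, x$config$n_replicates_per_group,
              x$config$n_replicates_per_group,
              x$config$n_mirna, x$config$n_mrna, x$config$n_lncrna,
              x$config$n_circrna, nrow(x$truth$planted_triplets)))
  invisible(x)
}

# assign each triplet a miRNA (recycled), an mRNA, and a ceRNA slot that
# alternates lncRNA/circRNA while the circRNA pool allows
plan_triplets <- function(config) {
  t_n <- config$n_planted_triplets
  if (t_n == 0L) {
    return(data.frame(mirna = integer(0), mrna = integer(0),
                      lnc = integer(0), circ = integer(0)))
  }
  use_circ <- config$n_circrna >= floor(t_n / 2) &&
    ceiling(t_n / 2) <= config$n_lncrna
  lnc <- circ <- rep(NA_integer_, t_n)
  li <- ci <- 0L
  for (i in seq_len(t_n)) {
    if (use_circ && i %% 2L == 0L) {
      ci <- ci + 1L; circ[i] <- ci
    } else {
      li <- li + 1L; lnc[i] <- li
    }
  }
  data.frame(
    mirna = ((seq_len(t_n) - 1L) %% config$n_mirna) + 1L,
    mrna = seq_len(t_n), lnc = lnc, circ = circ)
}

build_truth <- function(plan, ids, planted_rows) {
  empty_de <- data.frame(feature_id = character(0), class = character(0),
                         direction = character(0))
  planted_de <- if (length(planted_rows)) {
    unique(do.call(rbind, planted_rows))
  } else empty_de
  rownames(planted_de) <- NULL

  if (nrow(plan)) {
    ce_id <- ifelse(is.na(plan$lnc), ids$circRNA[plan$circ],
                    ids$lncRNA[plan$lnc])
    ce_class <- ifelse(is.na(plan$lnc), "circRNA", "lncRNA")
    triplets <- data.frame(ce_id = ce_id, ce_class = ce_class,
                           mirna_id = ids$miRNA[plan$mirna],
                           mrna_id = ids$mRNA[plan$mrna],
                           stringsAsFactors = FALSE)
    pairs <- unique(rbind(
      data.frame(mirna_id = triplets$mirna_id, target_id = triplets$ce_id),
      data.frame(mirna_id = triplets$mirna_id, target_id = triplets$mrna_id)))
    rownames(pairs) <- NULL
  } else {
    triplets <- data.frame(ce_id = character(0), ce_class = character(0),
                           mirna_id = character(0), mrna_id = character(0))
    pairs <- data.frame(mirna_id = character(0), target_id = character(0))
  }
  list(planted_de = planted_de, planted_triplets = triplets,
       planted_target_pairs = pairs)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# remove every occurrence of the given 6mer cores by point substitution
scrub_cores <- function(seq, cores) {
  if (length(cores) == 0L) return(seq)
  for (iter in 1:100) {
    hit <- NULL
    for (core in cores) {
      pos <- gregexpr(core, seq, fixed = TRUE)[[1]]
      if (pos[1] > 0L) { hit <- pos[1]; break }
    }
    if (is.null(hit)) return(seq)
    at <- hit + 2L  # mutate the middle of the offending core
    old <- substr(seq, at, at)
    substr(seq, at, at) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  stop("failed to scrub seed cores from a synthetic sequence")
}

has_any_core <- function(seq, cores) {
  any(vapply(cores, function(core) grepl(core, seq, fixed = TRUE), logical(1)))
}

mirna_core <- function(mirna_seq) {
  revcomp_dna(substr(as_dna(mirna_seq), 2L, 7L))
}

# 8mer site on the target: revcomp(miRNA 2-8) followed by an A opposite
# miRNA position 1
mirna_8mer_site <- function(mirna_seq) {
  paste0(revcomp_dna(substr(as_dna(mirna_seq), 2L, 8L)), "A")
}

generate_sequences <- function(config, ids, plan, truth) {
  # miRNA sequences with pairwise-distinct seed cores; additionally no
  # miRNA's core may occur anywhere inside another miRNA's 8mer site
  # (otherwise a planted site could never be free of foreign cores)
  site_windows <- function(s) {
    site <- mirna_8mer_site(s)
    vapply(1:3, function(i) substr(site, i, i + 5L), character(1))
  }
  mir_seqs <- character(0)
  cores <- character(0)
  windows <- character(0)
  for (id in ids$miRNA) {
    for (try in 1:1000) {
      s <- random_dna(MIRNA_SEQ_LEN)
      core <- mirna_core(s)
      w <- site_windows(s)
      if (!core %in% windows && !any(cores %in% w)) break
      if (try == 1000L) stop("failed to draw compatible miRNA seeds")
    }
    mir_seqs[id] <- s
    cores[id] <- core
    windows <- c(windows, w)
  }

  planted_mirs <- unique(truth$planted_target_pairs$mirna_id)
  screen <- unname(cores[planted_mirs])
  site_of <- stats::setNames(truth$planted_target_pairs$mirna_id,
                             truth$planted_target_pairs$target_id)

  target_ids <- c(ids$mRNA, ids$lncRNA, ids$circRNA)
  seqs <- character(0)
  for (id in target_ids) {
    if (id %in% names(site_of)) {
      site <- mirna_8mer_site(mir_seqs[[site_of[[id]]]])
      foreign <- setdiff(screen, cores[[site_of[[id]]]])
      # inserting the site can create a foreign core across the junction;
      # redraw until the sequence carries the planted site and nothing else
      for (try in 1:50) {
        s <- scrub_cores(random_dna(TARGET_SEQ_LEN), screen)
        at <- sample.int(TARGET_SEQ_LEN - nchar(site) + 1L, 1)
        substr(s, at, at + nchar(site) - 1L) <- site
        if (!has_any_core(s, foreign)) break
        if (try == 50L) stop("failed to plant a clean seed site")
      }
    } else {
      s <- scrub_cores(random_dna(TARGET_SEQ_LEN), screen)
    }
    seqs[id] <- s
  }
  c(mir_seqs, seqs)
}

# one chromosome; coding genes every 10 kb with a two-exon structure, and
# lncRNAs anchored round-robin to the five positional layouts
generate_transcripts <- function(ids) {
  models <- list()
  anchors <- list()
  for (i in seq_along(ids$mRNA)) {
    s <- 10000 + (i - 1L) * 10000
    strand <- if (i %% 2L == 1L) "+" else "-"
    models[[length(models) + 1L]] <- transcript_model(
      paste0(ids$mRNA[i], ".t1"), ids$mRNA[i], "chr1", strand,
      rbind(c(s, s + 400), c(s + 600, s + 999)), "protein_coding")
    anchors[[i]] <- list(s = s, strand = strand)
  }
  layouts <- c("sense_overlapping", "intronic", "antisense",
               "bidirectional", "intergenic")
  lnc_design <- character(0)
  for (i in seq_along(ids$lncRNA)) {
    anchor <- anchors[[((i - 1L) %% length(anchors)) + 1L]]
    s <- anchor$s
    layout <- layouts[((i - 1L) %% 5L) + 1L]
    flip <- function(x) if (x == "+") "-" else "+"
    geom <- switch(layout,
      sense_overlapping = list(exons = rbind(c(s + 100, s + 300)),
                               strand = anchor$strand),
      intronic = list(exons = rbind(c(s + 430, s + 560)),
                      strand = anchor$strand),
      antisense = list(exons = rbind(c(s + 50, s + 350)),
                       strand = flip(anchor$strand)),
      bidirectional = if (anchor$strand == "+") {
        list(exons = rbind(c(s - 700, s - 200)), strand = "-")
      } else {
        list(exons = rbind(c(s + 1199, s + 1699)), strand = "+")
      },
      intergenic = list(exons = rbind(c(s + 5000, s + 5400)),
                        strand = anchor$strand))
    models[[length(models) + 1L]] <- transcript_model(
      ids$lncRNA[i], ids$lncRNA[i], "chr1", geom$strand, geom$exons,
      "lncRNA_candidate")
    lnc_design[ids$lncRNA[i]] <- layout
  }
  list(models = models, lnc_design = lnc_design)
}
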