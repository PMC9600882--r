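#' Synthetic genome with planted regulator binding sites
#'
#' Generates a bacterial-genome-like sequence of tiled CDS features
#' separated by intergenic gaps, with instances of an IUPAC consensus
#' planted in randomly chosen gaps, and returns machine-readable ground
#' truth. Background sequence is i.i.d. with configurable GC content and is
#' rejection-sampled so that no background window on either strand comes
#' within `reject_hamming` mismatches of the consensus — scanning at the
#' default threshold therefore cannot produce background hits, making
#' planted-site precision exactly 1 by construction.
#'
#' Planted instances have their degenerate positions filled uniformly from
#' the allowed bases and then receive up to `ceiling(mutation_rate *
#' length)` substitutions at informative positions (each substitution to a
#' disallowed base, so the truth mismatch count is exact). Identical seed
#' and parameters give byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param consensus IUPAC consensus to plant.
#' @param n_intergenic number of intergenic gaps.
#' @param n_sites number of planted sites (at most one per gap).
#' @param mutation_rate per-site substitution budget as a fraction of motif
#'   length; the actual count is drawn uniformly from 0 to the ceiling.
#' @param gap_length intergenic gap length (nt).
#' @param cds_length CDS length (nt).
#' @param gc background GC content.
#' @param reject_hamming background windows within this many mismatches of
#'   the consensus are resampled.
#' @param seqid sequence name.
#' @return List: `genome` (named character), `features` (CDS data frame as
#'   from [read_annotations()]), `truth` (data frame: `seqid`, `gap`,
#'   `start`, `strand`, `mismatches`, `site`, `downstream_gene`, `offset`),
#'   `consensus`.
#' @export
gen_genome_with_sites <- function(seed,
                                  consensus = "TTGTTAANNNNTTAACAA",
                                  n_intergenic = 10,
                                  n_sites = 5,
                                  mutation_rate = 0.05,
                                  gap_length = 80,
                                  cds_length = 300,
                                  gc = 0.5,
                                  reject_hamming = 4,
                                  seqid = "chr") {
  set.seed(seed)
  L <- nchar(consensus)
  if (n_sites > n_intergenic) {
    stop("sizing error: at most one planted site per intergenic gap")
  }
  if (gap_length < L) {
    stop("sizing error: gaps shorter than the motif cannot hold a site")
  }
  bases <- c("A", "C", "G", "T")
  bprob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rand_seq <- function(n) {
    paste(sample(bases, n, replace = TRUE, prob = bprob), collapse = "")
  }
  cons_ch <- strsplit(toupper(consensus), "")[[1]]
  informative <- which(vapply(cons_ch,
                              function(c) length(IUPAC_CODES[[c]]) < 4,
                              logical(1)))
  mut_cap <- ceiling(mutation_rate * L)

  draw_site <- function() {
    site <- vapply(cons_ch, function(c) {
      allowed <- IUPAC_CODES[[c]]
      allowed[sample.int(length(allowed), 1)]
    }, character(1))
    n_mut <- sample.int(mut_cap + 1, 1) - 1
    pos <- if (n_mut > 0) sample(informative, n_mut) else integer(0)
    for (p in pos) {
      site[p] <- sample(setdiff(bases, IUPAC_CODES[[cons_ch[p]]]), 1)
    }
    list(site = paste(site, collapse = ""), mismatches = n_mut)
  }

  window_ok <- function(seq, site_local = NULL) {
    # no window (either strand) within reject_hamming of the consensus,
    # except windows overlapping a planted site
    check <- function(mm, n) {
      bad <- which(mm <= reject_hamming)
      if (is.null(site_local)) return(length(bad) == 0)
      # site occupies local 1-based positions site_local..site_local+L-1
      overl <- bad + L - 1 >= site_local & bad <= site_local + L - 1
      all(overl)
    }
    mm_f <- consensus_mismatch_windows(consensus, seq)
    if (!check(mm_f, nchar(seq))) return(FALSE)
    rc <- reverse_complement(seq)
    mm_r <- consensus_mismatch_windows(consensus, rc)
    bad_r <- which(mm_r <= reject_hamming)
    if (length(bad_r) == 0) return(TRUE)
    if (is.null(site_local)) return(FALSE)
    # map reverse windows onto forward coordinates
    starts_f <- nchar(seq) - bad_r - L + 2
    all(starts_f + L - 1 >= site_local & starts_f <= site_local + L - 1)
  }

  site_gaps <- sort(sample.int(n_intergenic, n_sites))
  gaps <- character(n_intergenic)
  truth_rows <- list()
  gap_site_local <- rep(NA_real_, n_intergenic)
  for (g in seq_len(n_intergenic)) {
    plant <- g %in% site_gaps
    for (attempt in seq_len(200)) {
      s <- rand_seq(gap_length)
      if (!plant) {
        if (window_ok(s)) break
      } else {
        ds <- draw_site()
        strand <- sample(c("+", "-"), 1)
        inserted <- if (strand == "+") ds$site else
          reverse_complement(ds$site)
        off <- sample.int(gap_length - L + 1, 1)
        substr(s, off, off + L - 1) <- inserted
        if (window_ok(s, site_local = off)) {
          gap_site_local[g] <- off
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            seqid = seqid, gap = g, local_start = off,
            strand = strand, mismatches = ds$mismatches,
            site = ds$site, stringsAsFactors = FALSE)
          break
        }
      }
      if (attempt == 200) stop("sizing error: cannot sample a clean gap")
    }
    gaps[g] <- s
  }

  # layout: CDS1 gap1 CDS2 gap2 ... CDSn gapn CDS(n+1)
  pieces <- character(0)
  feats <- list()
  pos <- 0
  gap_start <- numeric(n_intergenic)
  for (g in seq_len(n_intergenic + 1)) {
    cds <- rand_seq(cds_length)
    feats[[g]] <- data.frame(
      seqid = seqid, start = pos, end = pos + cds_length, strand = "+",
      type = "CDS", gene_id = sprintf("gene_%03d", g),
      stringsAsFactors = FALSE)
    pieces <- c(pieces, cds)
    pos <- pos + cds_length
    if (g <= n_intergenic) {
      gap_start[g] <- pos
      pieces <- c(pieces, gaps[g])
      pos <- pos + gap_length
    }
  }
  genome <- stats::setNames(paste(pieces, collapse = ""), seqid)
  features <- do.call(rbind, feats)

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(seqid = character(), gap = integer(),
               local_start = numeric(), strand = character(),
               mismatches = integer(), site = character(),
               stringsAsFactors = FALSE)
  if (nrow(truth)) {
    truth$start <- gap_start[truth$gap] + truth$local_start - 1
    truth$downstream_gene <- sprintf("gene_%03d", truth$gap + 1)
    gene_starts <- features$start[match(truth$downstream_gene,
                                        features$gene_id)]
    truth$offset <- truth$start - gene_starts
    truth$local_start <- NULL
  } else {
    truth$start <- numeric(0)
    truth$downstream_gene <- character(0)
    truth$offset <- numeric(0)
  }
  list(genome = genome, features = features, truth = truth,
       consensus = consensus)
}

# mismatch counts of every window of seq against an IUPAC consensus
consensus_mismatch_windows <- function(consensus, seq) {
  bases <- c("A", "C", "G", "T")
  cons_ch <- strsplit(toupper(consensus), "")[[1]]
  L <- length(cons_ch)
  codes <- match(strsplit(toupper(seq), "")[[1]], bases)
  nw <- length(codes) - L + 1
  if (nw < 1) return(integer(0))
  mm <- integer(nw)
  for (j in seq_len(L)) {
    disallowed <- !(bases %in% IUPAC_CODES[[cons_ch[j]]])
    mm <- mm + disallowed[codes[j:(j + nw - 1)]]
  }
  mm
}

#' Synthetic expression dataset with planted differential genes
#'
#' Emulates a two-condition (glucose vs lactate) bacterial RNA-seq
#' experiment at the gene level: baseline expression is log-normal, counts
#' are negative-binomial with a common dispersion, and `n_de` planted
#' differential genes receive log2 effects drawn from +-Uniform(1.5, 5).
#' The emitted differential table carries the *realized* sample log2 fold
#' change and an adjusted p-value computed inside the generator by a pooled
#' two-sample binomial count test (library-size offset) with
#' Benjamini-Hochberg correction — a deliberately simple stand-in for the
#' study's DESeq2 output, so the downstream pipeline can treat the columns
#' as given.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param n_de number of planted differential genes.
#' @param n_reps replicates per condition.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression
#'   parameters.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param effect_range range of |log2 effect| for planted genes.
#' @param frac_unannotated fraction of genes without a COG label.
#' @return List: `counts` (genes x samples), `lengths`, `table` (columns
#'   `gene_id`, `length`, `tpm_glucose`, `tpm_lactate`, `log2fc`, `padj`,
#'   `cog`), `truth` (planted gene ids and true effects).
#' @export
gen_expression_dataset <- function(seed,
                                   n_genes = 500,
                                   n_de = 50,
                                   n_reps = 3,
                                   baseline_meanlog = log(200),
                                   baseline_sdlog = 1.2,
                                   dispersion = 0.02,
                                   effect_range = c(1.5, 5),
                                   frac_unannotated = 0.1) {
  if (n_de > n_genes) stop("n_de must not exceed n_genes")
  set.seed(seed)
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  len <- sample(300:3000, n_genes, replace = TRUE)
  mu <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  effect <- rep(0, n_genes)
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
  if (n_de > 0) {
    effect[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, effect_range[1], effect_range[2])
  }
  mu_lac <- mu * 2^effect
  draw <- function(mu_vec) {
    vapply(seq_len(n_reps), function(r) {
      stats::rnbinom(n_genes, mu = mu_vec, size = 1 / dispersion)
    }, numeric(n_genes))
  }
  counts <- cbind(draw(mu), draw(mu_lac))
  colnames(counts) <- c(paste0("glucose_", seq_len(n_reps)),
                        paste0("lactate_", seq_len(n_reps)))
  rownames(counts) <- gene_id
  glu <- seq_len(n_reps) ; lac <- n_reps + seq_len(n_reps)

  tpm <- apply(counts, 2, tpm_from_counts, lengths = len)
  tpm_glucose <- rowMeans(tpm[, glu, drop = FALSE])
  tpm_lactate <- rowMeans(tpm[, lac, drop = FALSE])

  lib <- colSums(counts)
  cpm <- t(t(counts) / lib * 1e6)
  m_glu <- rowMeans(cpm[, glu, drop = FALSE])
  m_lac <- rowMeans(cpm[, lac, drop = FALSE])
  log2fc <- log2((m_lac + 0.5) / (m_glu + 0.5))

  tot_glu <- sum(lib[glu]) ; tot_lac <- sum(lib[lac])
  p_null <- tot_lac / (tot_glu + tot_lac)
  pval <- vapply(seq_len(n_genes), function(i) {
    x_lac <- sum(counts[i, lac]) ; tot <- x_lac + sum(counts[i, glu])
    if (tot == 0) return(1)
    stats::binom.test(x_lac, tot, p = p_null)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(pval, "BH")

  cog_pool <- c("C", "E", "F", "G", "H", "I", "J", "K", "L", "M",
                "O", "P", "T")
  cog <- sample(cog_pool, n_genes, replace = TRUE)
  cog[stats::runif(n_genes) < frac_unannotated] <- NA

  list(counts = counts,
       lengths = len,
       table = data.frame(gene_id = gene_id, length = len,
                          tpm_glucose = tpm_glucose,
                          tpm_lactate = tpm_lactate,
                          log2fc = log2fc, padj = padj, cog = cog,
                          stringsAsFactors = FALSE),
       truth = data.frame(gene_id = gene_id[de_idx],
                          effect = effect[de_idx],
                          stringsAsFactors = FALSE))
}

#' Noisy fermentation measurements
#'
#' Replicated substrate/product measurements around a true spectrum: each
#' species receives Gaussian noise with standard deviation `noise_sd` times
#' its true value, truncated at zero. The two published fermentation
#' equations are available as built-in truths.
#'
#' @param seed integer RNG seed.
#' @param truth `"eq1"`, `"eq2"`, or a named signed coefficient vector
#'   (negative = consumed) as accepted by [balance_fermentation()].
#' @param n_reps replicates.
#' @param noise_sd relative noise standard deviation (0 = exact).
#' @return Long data frame (`species`, `role`, `replicate`, `moles`) with
#'   the signed truth vector attached as attribute `"truth"`.
#' @export
gen_fermentation_measurements <- function(seed, truth = "eq1", n_reps = 3,
                                          noise_sd = 0.05) {
  if (noise_sd < 0) stop("noise sd must be nonnegative")
  set.seed(seed)
  if (is.character(truth)) {
    truth <- switch(truth,
      eq1 = c(glucose = -6, acetate = -2, caproate = 4, butyrate = 1),
      eq2 = c(lactate = -21, acetate = -2, caproate = 7, butyrate = 1),
      stop("unknown built-in spectrum: ", truth))
  }
  rows <- list()
  for (r in seq_len(n_reps)) {
    noisy <- abs(truth) * (1 + stats::rnorm(length(truth), 0, noise_sd))
    noisy <- pmax(noisy, 0)
    rows[[r]] <- data.frame(
      species = names(truth),
      role = ifelse(truth < 0, "consumed", "produced"),
      replicate = r, moles = noisy, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}
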