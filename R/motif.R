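#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Reverse complement of a sequence string
#'
#' Accepts plain ACGT or IUPAC degenerate letters.
#'
#' @param x single sequence string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  ch <- rev(strsplit(toupper(x), "")[[1]])
  comp <- IUPAC_COMPLEMENT[ch]
  if (anyNA(comp)) stop("invalid nucleotide character(s): ",
                        paste(unique(ch[is.na(comp)]), collapse = ", "))
  paste(comp, collapse = "")
}

#' Build a position weight matrix from an IUPAC consensus
#'
#' The degenerate consensus (the only motif description the seed literature
#' provides, e.g. the Clostridiaceae Rex box `TTGTTAANNNNTTAACAA` or the
#' LldR box `TGGTNNNACCA`) is converted to per-position base probabilities:
#' the `k` allowed bases at a position share `1 - (4 - k) * epsilon` equally
#' and each disallowed base receives `epsilon`. Log-odds are `log2(p /
#' background)`, so fully degenerate (N) positions score zero under the
#' uniform background.
#'
#' @param consensus IUPAC consensus string.
#' @param epsilon probability mass given to each disallowed base.
#' @param background per-base background probabilities (A, C, G, T).
#' @return A `motif_model`: list with `consensus`, `prob` (4 x L), `pwm`
#'   (4 x L log-odds, bits), `max_score`, `min_score`, `palindromic`.
#' @examples
#' consensus_to_pwm("TTGTTAANNNNTTAACAA")
#' @export
consensus_to_pwm <- function(consensus, epsilon = 1e-4,
                             background = rep(0.25, 4)) {
  if (!is.character(consensus) || length(consensus) != 1 ||
      nchar(consensus) == 0) {
    stop("consensus must be a single nonempty string")
  }
  if (epsilon <= 0 || epsilon >= 0.25) stop("epsilon must be in (0, 0.25)")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 probabilities summing to 1")
  }
  bases <- c("A", "C", "G", "T")
  names(background) <- bases
  ch <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_CODES))
  if (length(bad)) {
    stop("invalid IUPAC character(s) in consensus: ",
         paste(unique(bad), collapse = ", "))
  }
  L <- length(ch)
  prob <- matrix(0, 4, L, dimnames = list(bases, NULL))
  for (j in seq_len(L)) {
    allowed <- IUPAC_CODES[[ch[j]]]
    k <- length(allowed)
    prob[, j] <- epsilon
    prob[allowed, j] <- (1 - (4 - k) * epsilon) / k
  }
  pwm <- log2(prob / background)
  structure(list(consensus = paste(ch, collapse = ""),
                 epsilon = epsilon,
                 background = background,
                 prob = prob,
                 pwm = pwm,
                 max_score = sum(apply(pwm, 2, max)),
                 min_score = sum(apply(pwm, 2, min)),
                 palindromic =
                   paste(ch, collapse = "") == reverse_complement(consensus)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif model %s (%d positions%s)\n", x$consensus,
              ncol(x$pwm), if (x$palindromic) ", palindromic" else ""))
  cat(sprintf("  score range [%.2f, %.2f] bits\n", x$min_score, x$max_score))
  invisible(x)
}

#' Mismatches between a site and an IUPAC consensus
#'
#' Counts positions where the site base is not among the bases the consensus
#' code allows (N therefore matches everything).
#'
#' @param site ACGT string, same length as the consensus.
#' @param consensus IUPAC consensus string or a `motif_model`.
#' @return Integer mismatch count.
#' @examples
#' hamming_to_consensus("TTGCTAAAACTTTAACAA", "TTGTTAANNNNTTAACAA")  # 1
#' @export
hamming_to_consensus <- function(site, consensus) {
  if (inherits(consensus, "motif_model")) consensus <- consensus$consensus
  s <- strsplit(toupper(site), "")[[1]]
  k <- strsplit(toupper(consensus), "")[[1]]
  if (length(s) != length(k)) {
    stop("site length (", length(s), ") does not match consensus length (",
         length(k), ")")
  }
  sum(vapply(seq_along(s),
             function(i) !(s[i] %in% IUPAC_CODES[[k[i]]]),
             logical(1)))
}

#' Extract intergenic intervals from annotations
#'
#' Returns the maximal regions of each sequence not covered by any CDS
#' feature, each annotated with its downstream gene on either strand: the
#' nearest following gene on the plus strand and the nearest preceding gene
#' on the minus strand (a divergently transcribed pair thus shares one
#' upstream interval). Coordinates are 0-based half-open.
#'
#' @param features annotation data frame as returned by
#'   [read_annotations()]: columns `seqid`, `start`, `end`, `strand`,
#'   `gene_id` (0-based half-open).
#' @param genome named character vector of sequences (see [read_fasta()]).
#' @param min_length smallest interval retained (set to the motif length
#'   when scanning).
#' @return Data frame: `seqid`, `start`, `end`, `seq`, `down_plus_gene`,
#'   `down_plus_start`, `down_minus_gene`, `down_minus_end`.
#' @export
extract_intergenic <- function(features, genome, min_length = 1) {
  out <- list()
  for (sid in names(genome)) {
    slen <- nchar(genome[[sid]])
    f <- features[features$seqid == sid, , drop = FALSE]
    if (nrow(f) && (min(f$start) < 0 || max(f$end) > slen)) {
      stop("malformed annotation: feature outside sequence '", sid,
           "' (length ", slen, ")")
    }
    f <- f[order(f$start, f$end), , drop = FALSE]
    # merged CDS cover
    gaps <- list()
    pos <- 0
    if (nrow(f) == 0) {
      gaps[[1]] <- c(0, slen)
    } else {
      cover_end <- 0
      for (i in seq_len(nrow(f))) {
        if (f$start[i] > cover_end) {
          gaps[[length(gaps) + 1]] <- c(cover_end, f$start[i])
        }
        cover_end <- max(cover_end, f$end[i])
      }
      if (cover_end < slen) gaps[[length(gaps) + 1]] <- c(cover_end, slen)
    }
    for (g in gaps) {
      if (g[2] - g[1] < min_length) next
      plus <- f[f$strand == "+" & f$start >= g[2], , drop = FALSE]
      minus <- f[f$strand == "-" & f$end <= g[1], , drop = FALSE]
      dp <- if (nrow(plus)) plus[which.min(plus$start), ] else NULL
      dm <- if (nrow(minus)) minus[which.max(minus$end), ] else NULL
      out[[length(out) + 1]] <- data.frame(
        seqid = sid, start = g[1], end = g[2],
        seq = substr(genome[[sid]], g[1] + 1, g[2]),
        down_plus_gene = if (is.null(dp)) NA_character_ else dp$gene_id,
        down_plus_start = if (is.null(dp)) NA_real_ else dp$start,
        down_minus_gene = if (is.null(dm)) NA_character_ else dm$gene_id,
        down_minus_end = if (is.null(dm)) NA_real_ else dm$end,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(seqid = character(), start = numeric(),
                      end = numeric(), seq = character(),
                      down_plus_gene = character(),
                      down_plus_start = numeric(),
                      down_minus_gene = character(),
                      down_minus_end = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# raw log-odds scores of all windows of seq (character) against the pwm;
# windows containing non-ACGT bases score NA
pwm_window_scores <- function(model, seq) {
  bases <- c("A", "C", "G", "T")
  codes <- match(strsplit(toupper(seq), "")[[1]], bases)
  L <- ncol(model$pwm)
  nw <- length(codes) - L + 1
  if (nw < 1) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + model$pwm[, j][codes[j:(j + nw - 1)]]
  }
  sc
}

#' Scan intergenic intervals for motif hits
#'
#' Scores every window of every interval on both strands against the PWM and
#' reports windows whose min-max-normalized score `(score - min) / (max -
#' min)` reaches `threshold`. For a palindromic motif (one equal to its own
#' reverse complement, like the Rex box) minus-strand windows duplicate the
#' plus-strand scores exactly, so only the plus-strand representative is
#' reported. Offsets are computed relative to the downstream gene's
#' translation start (negative = upstream, the 5'-UTR convention); when both
#' strands carry a downstream gene the nearer one is used.
#'
#' @param motif a `motif_model` (or consensus string).
#' @param intervals data frame from [extract_intergenic()].
#' @param threshold fraction of the min-max score range, in (0, 1].
#' @param both_strands scan the minus strand as well.
#' @return Data frame of hits: `seqid`, `start`, `end`, `strand`, `site`,
#'   `score` (raw bits), `score_scaled`, `downstream_gene`, `offset`.
#' @export
scan_sequences <- function(motif, intervals, threshold = 0.7,
                           both_strands = TRUE) {
  if (is.character(motif)) motif <- consensus_to_pwm(motif)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  L <- ncol(motif$pwm)
  rng <- motif$max_score - motif$min_score
  cutoff <- motif$min_score + threshold * rng
  hits <- list()
  add_hit <- function(iv, local_start, strand, site, score) {
    s <- iv$start + local_start - 1
    e <- s + L
    off_p <- if (!is.na(iv$down_plus_start)) s - iv$down_plus_start else NA
    off_m <- if (!is.na(iv$down_minus_end)) iv$down_minus_end - e else NA
    if (!is.na(off_p) && (is.na(off_m) || abs(off_p) <= abs(off_m))) {
      gene <- iv$down_plus_gene ; off <- off_p
    } else if (!is.na(off_m)) {
      gene <- iv$down_minus_gene ; off <- off_m
    } else {
      gene <- NA_character_ ; off <- NA_real_
    }
    data.frame(seqid = iv$seqid, start = s, end = e, strand = strand,
               site = site, score = score,
               score_scaled = (score - motif$min_score) / rng,
               downstream_gene = gene, offset = off,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    if (nchar(iv$seq) < L) {
      message("skipping interval ", iv$seqid, ":", iv$start, "-", iv$end,
              " (shorter than the motif)")
      next
    }
    fwd <- pwm_window_scores(motif, iv$seq)
    for (w in which(!is.na(fwd) & fwd >= cutoff)) {
      hits[[length(hits) + 1]] <-
        add_hit(iv, w, "+", substr(iv$seq, w, w + L - 1), fwd[w])
    }
    if (both_strands && !motif$palindromic) {
      rc <- reverse_complement(iv$seq)
      rev <- pwm_window_scores(motif, rc)
      n <- nchar(iv$seq)
      for (w in which(!is.na(rev) & rev >= cutoff)) {
        # window w on the reverse strand starts at n - w - L + 2 on the
        # forward strand (1-based local)
        local <- n - w - L + 2
        hits[[length(hits) + 1]] <-
          add_hit(iv, local, "-", substr(rc, w, w + L - 1), rev[w])
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(seqid = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      site = character(), score = numeric(),
                      score_scaled = numeric(),
                      downstream_gene = character(), offset = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Binding-site report
#'
#' Formats scan hits as a table of predicted binding sites: downstream
#' (operon-leading) gene, position of the site relative to that gene's
#' translation start (negative = upstream), site sequence and score, sorted
#' by score descending with ties broken by leftmost coordinate.
#'
#' @param hits data frame from [scan_sequences()].
#' @param path optional TSV file to write.
#' @return Data frame: `operon_first_gene`, `position`, `site`, `score`,
#'   `score_scaled`.
#' @export
site_report <- function(hits, path = NULL) {
  ord <- order(-hits$score, hits$seqid, hits$start)
  rep <- data.frame(operon_first_gene = hits$downstream_gene[ord],
                    position = hits$offset[ord],
                    site = hits$site[ord],
                    score = hits$score[ord],
                    score_scaled = hits$score_scaled[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(rep))
  }
  rep
}

#' Base-count matrix of reported sites
#'
#' Aligned integer counts of A, C, G, T at each motif position over a set of
#' hit site sequences, suitable for external sequence-logo rendering.
#'
#' @param sites character vector of equal-length site strings (e.g.
#'   `hits$site`).
#' @return Integer matrix, motif length x 4 (columns A, C, G, T).
#' @export
site_count_matrix <- function(sites) {
  if (length(sites) == 0) stop("no sites supplied")
  L <- unique(nchar(sites))
  if (length(L) != 1) stop("sites must all have the same length")
  bases <- c("A", "C", "G", "T")
  m <- matrix(0L, L, 4, dimnames = list(NULL, bases))
  for (s in sites) {
    ch <- strsplit(toupper(s), "")[[1]]
    for (j in seq_len(L)) {
      if (ch[j] %in% bases) m[j, ch[j]] <- m[j, ch[j]] + 1L
    }
  }
  m
}
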