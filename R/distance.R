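# Uncorrected pairwise distance screening of aligned sequences:
# within/among-lineage summaries, threshold clustering into candidate
# lineages, and phased-allele sharing reports.

#' A labelled set of aligned sequences
#'
#' Light container tying aligned sequences (equal-length character strings
#' over the IUPAC alphabet plus gaps) to optional lineage labels.
#'
#' @param seqs named character vector of aligned sequences.
#' @param lineage optional vector of lineage labels (recycled names of
#'   `seqs` are used to align them).
#' @param locus locus name.
#' @return An object of class `sequence_set`.
#' @export
sequence_set <- function(seqs, lineage = NULL, locus = "16S") {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_("sequences must be named")
  len <- unique(nchar(seqs))
  if (length(len) != 1) stop_("all sequences must have equal aligned length")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTURYSWKMBDHVN.-]", seqs)
  if (any(bad))
    stop_("sequence '%s' contains non-IUPAC characters", names(seqs)[bad][1])
  if (!is.null(lineage)) {
    if (is.null(names(lineage))) {
      if (length(lineage) != length(seqs))
        stop_("lineage labels do not match the sequences")
      names(lineage) <- names(seqs)
    }
    lineage <- lineage[names(seqs)]
  }
  structure(list(seqs = seqs, lineage = lineage, locus = locus,
                 length = len), class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set> %d sequences x %d aligned sites (%s)\n",
              length(x$seqs), x$length, x$locus))
  if (!is.null(x$lineage))
    cat("  lineages:", paste(names(table(x$lineage)), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write FASTA alignments
#'
#' Thin wrappers over [ape::read.FASTA()] / [ape::write.FASTA()] producing
#' and consuming `sequence_set` objects. Lineage labels can be supplied as
#' a CSV with columns `id` and `lineage`.
#'
#' @param path FASTA file path.
#' @param labels optional path to a `id,lineage` CSV, or a named vector.
#' @param x a `sequence_set`.
#' @return `read_fasta` returns a `sequence_set`; `write_fasta` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path, labels = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  names(seqs) <- names(dna)
  lin <- NULL
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
      tab <- utils::read.csv(labels, stringsAsFactors = FALSE)
      lin <- stats::setNames(as.character(tab$lineage), tab$id)
    } else lin <- labels
  }
  sequence_set(seqs, lineage = lin)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "sequence_set")) x$seqs else x
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(seqs))
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  invisible(path)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: alignment columns where either sequence has a gap or
#' anything other than an unambiguous A/C/G/T base (IUPAC ambiguity codes
#' included) are excluded; the distance is the proportion of mismatches
#' among the remaining columns.
#'
#' @param a,b aligned sequences (equal-length character strings, or
#'   character vectors of single bases).
#' @return A list with `distance` (proportion) and `n_compared` (columns
#'   compared). Zero comparable columns is an error.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25 over 4 sites
#' @export
p_distance <- function(a, b) {
  av <- if (length(a) == 1) strsplit(toupper(a), "")[[1]] else toupper(a)
  bv <- if (length(b) == 1) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(av) != length(bv)) stop_("sequences differ in aligned length")
  acgt <- c("A", "C", "G", "T")
  ok <- av %in% acgt & bv %in% acgt
  n <- sum(ok)
  if (n == 0) stop_("no comparable (unambiguous, ungapped) columns")
  list(distance = sum(av[ok] != bv[ok]) / n, n_compared = n)
}

#' Pairwise p-distance matrix for a sequence set
#'
#' @param x a `sequence_set` (or named character vector of aligned
#'   sequences).
#' @return An object of class `p_dist`: symmetric `distance` matrix
#'   (proportions, zero diagonal), matching `n_compared` matrix, and the
#'   lineage labels when available.
#' @export
p_distance_matrix <- function(x) {
  ss <- if (inherits(x, "sequence_set")) x else sequence_set(x)
  n <- length(ss$seqs)
  chars <- do.call(rbind, strsplit(unname(ss$seqs), ""))
  valid <- chars == "A" | chars == "C" | chars == "G" | chars == "T"
  D <- matrix(0, n, n, dimnames = list(names(ss$seqs), names(ss$seqs)))
  N <- matrix(ss$length, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    nc <- sum(ok)
    if (nc == 0) stop_("no comparable columns between '%s' and '%s'",
                       names(ss$seqs)[i], names(ss$seqs)[j])
    d <- sum(chars[i, ok] != chars[j, ok]) / nc
    D[i, j] <- D[j, i] <- d
    N[i, j] <- N[j, i] <- nc
  }
  structure(list(distance = D, n_compared = N, lineage = ss$lineage,
                 locus = ss$locus), class = "p_dist")
}

#' @export
print.p_dist <- function(x, ...) {
  cat(sprintf("<p_dist> %d sequences (%s); distances %.2f-%.2f%%\n",
              nrow(x$distance), x$locus,
              100 * min(x$distance[upper.tri(x$distance)]),
              100 * max(x$distance[upper.tri(x$distance)])))
  invisible(x)
}

#' Within- and among-lineage divergence summary
#'
#' Summarizes a p-distance matrix by lineage: per-lineage within statistics
#' over intra-label pairs (flagged undefined for singleton lineages) and
#' per-pair-of-lineages among statistics. Printed values are percentages to
#' 2 decimals; the underlying proportions are kept.
#'
#' @param pd a `p_dist` object.
#' @param labels lineage labels per sequence (default: those stored in
#'   `pd`). Every sequence must be labelled.
#' @return An object of class `divergence_summary`: data frames `within`
#'   (group, n_pairs, min, max, mean) and `among` (group1, group2, n_pairs,
#'   min, max, mean), plus overall `among_range` and `within_range`.
#' @export
group_divergence <- function(pd, labels = NULL) {
  labels <- labels %||% pd$lineage
  if (is.null(labels)) stop_("no lineage labels available")
  ids <- rownames(pd$distance)
  if (!is.null(names(labels))) labels <- labels[ids]
  if (any(is.na(labels) | !nzchar(as.character(labels))))
    stop_("every sequence must carry a lineage label")
  labels <- as.character(labels)
  D <- pd$distance
  groups <- sort(unique(labels))
  stat <- function(v) if (length(v)) c(min = min(v), max = max(v), mean = mean(v))
                      else c(min = NA_real_, max = NA_real_, mean = NA_real_)
  within <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(labels == g)
    v <- if (length(idx) > 1) D[idx, idx][upper.tri(D[idx, idx])] else numeric(0)
    data.frame(group = g, n = length(idx), n_pairs = length(v),
               t(stat(v)))
  }))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  among <- do.call(rbind, lapply(pairs, function(gg) {
    v <- as.vector(D[labels == gg[1], labels == gg[2], drop = FALSE])
    data.frame(group1 = gg[1], group2 = gg[2], n_pairs = length(v), t(stat(v)))
  }))
  structure(list(within = within, among = among,
                 within_range = range(within$max, na.rm = TRUE),
                 among_range = c(min(among$min), max(among$max))),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f", 100 * v)
  cat("<divergence_summary>\n")
  cat(sprintf("  among lineages:  %s-%s%% (uncorrected p)\n",
              fmt(x$among_range[1]), fmt(x$among_range[2])))
  wr <- x$within_range
  if (all(is.finite(wr)))
    cat(sprintf("  within lineages: %s-%s%% (max per lineage)\n",
                fmt(wr[1]), fmt(wr[2])))
  singles <- x$within$group[x$within$n_pairs == 0]
  if (length(singles))
    cat("  within undefined (singletons):", paste(singles, collapse = ", "), "\n")
  invisible(x)
}

#' Threshold clustering of sequences into candidate lineages
#'
#' Single-linkage agglomeration on the p-distance matrix: clusters are
#' merged while the minimum inter-cluster distance does not exceed the
#' cutoff, so identical sequences always share a cluster and the partition
#' coarsens monotonically as the cutoff grows.
#'
#' @param pd a `p_dist` object.
#' @param cutoff distance cutoff as a proportion (default 0.03, the common
#'   16S candidate-species screen).
#' @return An integer membership vector named by sequence id.
#' @export
threshold_cluster <- function(pd, cutoff = 0.03) {
  D <- stats::as.dist(pd$distance)
  hc <- stats::hclust(D, method = "single")
  stats::cutree(hc, h = cutoff)
}

#' Cross-lineage sharing of phased alleles
#'
#' Reports every haplotype observed in more than one lineage. Each
#' individual must carry exactly two phased haplotypes per locus.
#'
#' @param haps data frame with columns `individual`, `locus`, `allele`
#'   (haplotype string) and `lineage`.
#' @return A list with `report` (locus, allele, lineages, n_lineages) and
#'   `n_events`, the count of cross-lineage sharing events.
#' @export
allele_sharing <- function(haps) {
  need <- c("individual", "locus", "allele", "lineage")
  miss <- setdiff(need, names(haps))
  if (length(miss)) stop_("missing column(s): %s", paste(miss, collapse = ", "))
  cnt <- table(haps$individual, haps$locus)
  if (any(cnt != 0 & cnt != 2)) {
    bad <- which(cnt != 0 & cnt != 2, arr.ind = TRUE)[1, ]
    stop_("individual '%s' has %d haplotypes at locus '%s' (expected 2)",
          rownames(cnt)[bad[1]], cnt[bad[1], bad[2]], colnames(cnt)[bad[2]])
  }
  key <- interaction(haps$locus, haps$allele, drop = TRUE)
  rep_list <- lapply(split(haps, key), function(d) {
    lins <- sort(unique(as.character(d$lineage)))
    if (length(lins) < 2) return(NULL)
    data.frame(locus = d$locus[1], allele = d$allele[1],
               lineages = paste(lins, collapse = ","),
               n_lineages = length(lins))
  })
  report <- do.call(rbind, rep_list)
  if (is.null(report))
    report <- data.frame(locus = character(0), allele = character(0),
                         lineages = character(0), n_lineages = integer(0))
  rownames(report) <- NULL
  list(report = report, n_events = nrow(report))
}
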