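## BioID enrichment chain: shared-count distribution -> dNSAF ->
## bait-vs-control enrichment -> three-part hit filter -> intersections.

.protein_list <- function(protein_ids) {
  if (is.list(protein_ids)) return(lapply(protein_ids, as.character))
  strsplit(as.character(protein_ids), ";", fixed = TRUE)
}

.count_columns <- function(peptides) {
  setdiff(colnames(peptides), c("peptide_id", "protein_ids"))
}

.check_peptides <- function(peptides) {
  need <- c("peptide_id", "protein_ids")
  if (!all(need %in% colnames(peptides)))
    stop("peptide table needs columns 'peptide_id' and 'protein_ids'")
  cc <- .count_columns(peptides)
  if (length(cc) == 0) stop("peptide table has no count columns")
  cnt <- as.matrix(peptides[, cc, drop = FALSE])
  storage.mode(cnt) <- "double"
  if (any(!is.finite(cnt)) || any(cnt < 0))
    stop("spectral counts must be finite and non-negative")
  prot <- .protein_list(peptides$protein_ids)
  if (any(lengths(prot) == 0L))
    stop("every peptide must map to at least one protein")
  list(counts = cnt, proteins = prot)
}

#' Distribute shared peptide counts to proteins
#'
#' Converts peptide-level spectral counts into per-protein distributed
#' spectral counts (dSpC). A peptide mapping to a single protein assigns its
#' counts wholly to that protein. A peptide shared between several proteins
#' has its count in each replicate split among them in proportion to each
#' protein's unique spectral count in that same replicate; when none of the
#' sharing proteins has unique evidence in a replicate the count is split
#' equally (the only symmetric rule that still conserves counts). Totals are
#' conserved per replicate.
#'
#' @param peptides data.frame of peptide evidence with columns
#'   \code{peptide_id}, \code{protein_ids} (semicolon-separated identifiers,
#'   or a list column), and one numeric count column per replicate run.
#' @param proteins data.frame with columns \code{protein_id} and
#'   \code{length_aa}; every protein referenced by a peptide must appear.
#' @return numeric matrix of dSpC values, one row per protein (rownames are
#'   protein ids, in \code{proteins$protein_id} order) and one column per
#'   count column of \code{peptides}.
#' @examples
#' peps <- data.frame(peptide_id = c("p1", "p2", "p3"),
#'                    protein_ids = c("A", "B", "A;B"),
#'                    bait_1 = c(4, 4, 2))
#' prots <- data.frame(protein_id = c("A", "B"), length_aa = c(100, 100))
#' distributeSharedCounts(peps, prots)  # A and B each get 4 + 1
#' @export
distributeSharedCounts <- function(peptides, proteins) {
  pe <- .check_peptides(peptides)
  ids <- as.character(proteins$protein_id)
  if (anyDuplicated(ids)) stop("duplicated protein_id in protein table")
  unknown <- setdiff(unique(unlist(pe$proteins)), ids)
  if (length(unknown) > 0)
    stop("peptides reference unknown proteins: ",
         paste(unknown, collapse = ", "))
  nrep <- ncol(pe$counts)
  idx <- lapply(pe$proteins, match, ids)
  shared <- lengths(idx) > 1L

  # unique spectral counts per protein per replicate
  uspc <- matrix(0, nrow = length(ids), ncol = nrep,
                 dimnames = list(ids, colnames(pe$counts)))
  if (any(!shared)) {
    ui <- unlist(idx[!shared])
    s <- rowsum(pe$counts[!shared, , drop = FALSE], group = ui)
    uspc[as.integer(rownames(s)), ] <- s
  }

  dspc <- uspc
  if (any(shared)) {
    sidx <- which(shared)
    for (i in sidx) {
      k <- idx[[i]]
      u <- uspc[k, , drop = FALSE]
      tot <- colSums(u)
      w <- sweep(u, 2, ifelse(tot > 0, tot, 1), "/")
      w[, tot == 0] <- 1 / length(k)
      dspc[k, ] <- dspc[k, ] + w * rep(pe$counts[i, ], each = length(k))
    }
  }
  dspc
}

#' Compute dNSAF from distributed spectral counts
#'
#' The distributed normalized spectral abundance factor for protein \eqn{k}
#' in one replicate is \eqn{(dSpC_k / L_k) / \sum_j (dSpC_j / L_j)} where
#' \eqn{L_k} is the protein length in amino acids. A replicate with no
#' counts at all yields an all-zero column.
#'
#' @param dspc numeric matrix of distributed spectral counts (proteins by
#'   replicates, rownames are protein ids), as from
#'   [distributeSharedCounts()].
#' @param proteins data.frame with \code{protein_id} and \code{length_aa}.
#' @return numeric matrix of dNSAF values with the shape of \code{dspc}.
#' @export
computeDnsaf <- function(dspc, proteins) {
  L <- proteins$length_aa[match(rownames(dspc), proteins$protein_id)]
  if (any(is.na(L))) stop("dSpC rows missing from protein table")
  if (any(!is.finite(L)) || any(L <= 0)) stop("length_aa must be positive")
  saf <- dspc / L
  tot <- colSums(saf)
  sweep(saf, 2, ifelse(tot > 0, tot, 1), "/")
}

#' Build a DnsafExperiment from peptide evidence
#'
#' Runs [distributeSharedCounts()] and [computeDnsaf()] and packages the
#' result. Condition labels are taken from the count column names: anything
#' before the final underscore is the condition, the suffix the replicate
#' (e.g. \code{"bait_3"}); pass \code{conditions} to override.
#'
#' @inheritParams distributeSharedCounts
#' @param conditions optional character vector, one label per count column.
#' @return a \linkS4class{DnsafExperiment}.
#' @export
dnsafExperiment <- function(peptides, proteins, conditions = NULL) {
  dspc <- distributeSharedCounts(peptides, proteins)
  dn <- computeDnsaf(dspc, proteins)
  cols <- colnames(dspc)
  if (is.null(conditions)) conditions <- sub("_[0-9]+$", "", cols)
  if (length(conditions) != ncol(dspc))
    stop("'conditions' must name every count column")
  rep_id <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dSpC = dspc, dNSAF = dn),
    rowData = S4Vectors::DataFrame(
      length_aa = proteins$length_aa[match(rownames(dspc),
                                           proteins$protein_id)]),
    colData = S4Vectors::DataFrame(condition = conditions,
                                   replicate = as.integer(rep_id),
                                   row.names = cols))
  methods::new("DnsafExperiment", se)
}

#' Mean over nonzero replicate values
#'
#' Average abundance the way label-free spectral counting reports it:
#' the arithmetic mean over the replicates in which the protein was
#' observed (nonzero dNSAF). An all-zero vector averages to 0.
#'
#' @param x numeric vector of per-replicate values.
#' @return scalar mean of the nonzero entries, or 0 if there are none.
#' @export
averageNonzero <- function(x) {
  nz <- x[x != 0]
  if (length(nz) == 0) 0 else mean(nz)
}

# Student/Welch two-sample two-tailed t, with defined limits for the
# degenerate zero-variance cases (t.test() errors on constant data).
.two_sample_p <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("t-test needs at least 2 replicates per condition")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    return(list(p = p, degenerate = TRUE))
  }
  p <- stats::t.test(a, b, var.equal = !welch)$p.value
  list(p = p, degenerate = FALSE)
}

#' Bait-versus-control enrichment per protein
#'
#' For every protein in the experiment computes the average dNSAF in the
#' bait and control conditions (over nonzero replicates), their ratio as
#' fold enrichment (+Inf when the protein is absent from the control but
#' present in the bait), a two-tailed two-sample t-test p value (classic
#' equal-variance Student's t by default, Welch optionally), replicate
#' presence counts, and derived display columns (log2 fold with a
#' configurable cap for the infinite case, -log10 p, and a
#' Benjamini-Hochberg adjusted p provided for information only -- the hit
#' filter uses the raw p).
#'
#' By default the values entering the t-test follow the same
#' nonzero-replicates convention as the averages: each condition
#' contributes the dNSAF values of the replicates in which the protein was
#' observed, falling back to the full vector (zeros included) when a
#' condition has fewer than two nonzero replicates, so the test is always
#' defined. A missing protein in one replicate of spectral-count data is
#' an identification failure rather than a measured zero abundance, and
#' treating such zeros as measurements swamps the between-condition signal
#' with identification noise. Set \code{zeros = "include"} to test the
#' full per-replicate vectors throughout.
#'
#' @param x a \linkS4class{DnsafExperiment}.
#' @param bait,control condition labels present in \code{conditionLabels(x)}.
#' @param welch use Welch's t-test instead of Student's.
#' @param zeros \code{"exclude"} (default) tests the nonzero replicate
#'   values per condition, \code{"include"} the full vectors.
#' @param logValues t-test on log-transformed (log(x + half the smallest
#'   nonzero dNSAF)) values instead of raw ones.
#' @param log2Cap display cap substituted for infinite log2 fold.
#' @return a [S4Vectors::DataFrame] with one row per protein: columns
#'   \code{protein_id}, \code{avg_dnsaf_bait}, \code{avg_dnsaf_control},
#'   \code{fold_enrichment}, \code{log2_fold}, \code{p_value},
#'   \code{neg_log10_p}, \code{p_adj_bh}, \code{n_present_bait},
#'   \code{n_present_control}, \code{degenerate}.
#' @export
enrichmentTest <- function(x, bait = "bait", control = "control",
                           welch = FALSE, zeros = c("exclude", "include"),
                           logValues = FALSE, log2Cap = 10) {
  zeros <- match.arg(zeros)
  cond <- conditionLabels(x)
  if (!bait %in% cond || !control %in% cond)
    stop("bait/control condition not found in experiment")
  dn <- dNSAF(x)
  B <- dn[, cond == bait, drop = FALSE]
  C <- dn[, cond == control, drop = FALSE]
  avgB <- unname(apply(B, 1, averageNonzero))
  avgC <- unname(apply(C, 1, averageNonzero))
  fold <- ifelse(avgC > 0, avgB / avgC, ifelse(avgB > 0, Inf, 0))
  tv <- if (logValues) {
    eps <- min(dn[dn > 0], Inf) / 2
    list(B = log(B + eps), C = log(C + eps))
  } else list(B = B, C = C)
  pick <- function(v, raw) {
    if (zeros == "include") return(v)
    nz <- v[raw != 0]
    if (length(nz) >= 2) nz else v
  }
  pt <- lapply(seq_len(nrow(dn)), function(i)
    .two_sample_p(pick(tv$B[i, ], B[i, ]), pick(tv$C[i, ], C[i, ]),
                  welch = welch))
  p <- vapply(pt, `[[`, numeric(1), "p")
  log2f <- ifelse(is.infinite(fold), log2Cap,
                  ifelse(fold > 0, log2(fold), NA_real_))
  S4Vectors::DataFrame(
    protein_id = rownames(dn),
    avg_dnsaf_bait = avgB,
    avg_dnsaf_control = avgC,
    fold_enrichment = fold,
    log2_fold = log2f,
    p_value = p,
    neg_log10_p = -log10(p),
    p_adj_bh = stats::p.adjust(p, method = "BH"),
    n_present_bait = as.integer(rowSums(B > 0)),
    n_present_control = as.integer(rowSums(C > 0)),
    degenerate = vapply(pt, `[[`, logical(1), "degenerate"))
}

#' Apply the three-part interactome hit filter
#'
#' A protein is a hit when all three clauses hold: (i) fold enrichment of
#' at least \code{foldThreshold} over the control, or complete absence from
#' the control with presence in the bait (infinite fold); (ii) t-test
#' p value below \code{pThreshold}; and (iii) nonzero dNSAF in at least
#' \code{minPresent} bait replicates. No multiple-testing correction is
#' applied in the verdict.
#'
#' @param results output of [enrichmentTest()].
#' @param foldThreshold minimum fold enrichment (default 3).
#' @param pThreshold significance level for the raw p value (default 0.05).
#' @param minPresent minimum bait replicates with nonzero dNSAF (default 3).
#' @param verbose message the per-clause attrition (how many proteins each
#'   filter clause removes on its own).
#' @return \code{results} with a logical \code{is_hit} column appended.
#' @export
callHits <- function(results, foldThreshold = 3, pThreshold = 0.05,
                     minPresent = 3, verbose = FALSE) {
  if (!is.finite(foldThreshold) || foldThreshold < 1)
    stop("foldThreshold must be finite and >= 1")
  if (pThreshold <= 0 || pThreshold > 1)
    stop("pThreshold must be in (0, 1]")
  if (minPresent < 0) stop("minPresent must be non-negative")
  absent_ctrl <- results$avg_dnsaf_control == 0 & results$avg_dnsaf_bait > 0
  c_fold <- results$fold_enrichment >= foldThreshold | absent_ctrl
  c_p <- results$p_value < pThreshold
  c_pres <- results$n_present_bait >= minPresent
  results$is_hit <- c_fold & c_p & c_pres
  if (verbose)
    message(sprintf(
      "%d proteins: %d pass fold/absence, %d pass p < %g, %d pass presence >= %d; %d hits",
      nrow(results), sum(c_fold), sum(c_p), pThreshold, sum(c_pres),
      minPresent, sum(results$is_hit)))
  results
}

#' Intersections of hit sets across bait datasets
#'
#' Assigns every protein in the union of hits to the exact subset of baits
#' in which it is a hit, and reports the count and protein list for every
#' non-empty subset of baits (empty subsets are reported with count 0 so
#' the table always enumerates all 2^k - 1 combinations). The subsets
#' partition the union, so the counts sum to its size.
#'
#' @param hitSets named list of character vectors of hit protein ids, one
#'   per bait dataset.
#' @return data.frame with columns \code{baits} (ampersand-joined bait
#'   names), \code{n_baits}, \code{count}, and \code{proteins}
#'   (semicolon-joined ids).
#' @export
intersectHits <- function(hitSets) {
  if (length(hitSets) < 1 || is.null(names(hitSets)))
    stop("hitSets must be a non-empty named list")
  baits <- names(hitSets)
  hitSets <- lapply(hitSets, unique)
  universe <- unique(unlist(hitSets))
  member <- vapply(hitSets, function(h) universe %in% h,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, baits))
  key <- apply(member, 1, function(m) paste(baits[m], collapse = "&"))
  subsets <- unlist(lapply(seq_along(baits), function(k)
    utils::combn(baits, k, FUN = paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  count <- vapply(subsets, function(s) sum(key == s), integer(1))
  prots <- vapply(subsets, function(s)
    paste(sort(universe[key == s]), collapse = ";"), character(1))
  data.frame(baits = subsets,
             n_baits = lengths(strsplit(subsets, "&", fixed = TRUE)),
             count = count, proteins = prots,
             stringsAsFactors = FALSE)
}

## sentinel used for infinite fold enrichment in exported tables
.INF_TOKEN <- "Inf"

#' Export node and edge tables for graph viewers
#'
#' Writes a node table (one row per protein with enrichment statistics and
#' hit flag) and a bait-prey edge table (one edge per hit) as tab-delimited
#' UTF-8 text. Infinite fold enrichment is written with the sentinel token
#' \code{"Inf"} and restored on re-import; the capped \code{log2_fold}
#' display value is exported as computed.
#'
#' @param results output of [callHits()].
#' @param bait name used for the bait node in the edge table.
#' @param dir output directory (created if missing).
#' @param annotations optional named character vector of category tags,
#'   names are protein ids.
#' @return invisibly, the paths of the two files written
#'   (\code{nodes.tsv}, \code{edges.tsv}).
#' @export
exportInteractionTables <- function(results, bait, dir, annotations = NULL) {
  if (is.null(results$is_hit)) stop("run callHits() before exporting")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- as.data.frame(results)
  nodes$category <- if (is.null(annotations)) NA_character_ else
    unname(annotations[nodes$protein_id])
  npath <- file.path(dir, "nodes.tsv")
  epath <- file.path(dir, "edges.tsv")
  out <- nodes
  out$fold_enrichment <- ifelse(is.infinite(out$fold_enrichment),
                                .INF_TOKEN,
                                format(out$fold_enrichment, digits = 17))
  ok <- tryCatch({
    utils::write.table(out, npath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    edges <- data.frame(bait = bait,
                        prey = nodes$protein_id[nodes$is_hit],
                        stringsAsFactors = FALSE)
    utils::write.table(edges, epath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e)
    stop("failed writing interaction tables to '", dir, "': ",
         conditionMessage(e)))
  invisible(c(nodes = npath, edges = epath))
}

#' Re-import an exported node table
#'
#' Inverse of [exportInteractionTables()]: reads \code{nodes.tsv} back into
#' a data.frame with numeric columns restored, including \code{Inf}
#' sentinels in \code{fold_enrichment}.
#'
#' @param path path to a \code{nodes.tsv} written by
#'   [exportInteractionTables()].
#' @return data.frame of enrichment results.
#' @export
readInteractionNodes <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$fold_enrichment <- as.numeric(x$fold_enrichment)
  x
}
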