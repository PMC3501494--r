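#' Build a 2xK switch table for one gene
#'
#' Rows are the two samples (row scores: 1 = control, 2 = case), columns
#' the gene's tandem poly(A) sites ordered from shortest
#' to longest tandem UTR, cells the read counts. Genes are skipped when
#' they have fewer than two tandem sites (`single_site`), are not
#' co-expressed, i.e. one sample contributed no reads (`not_coexpressed`),
#' or the table total is below `minTotal` reads (`low_count`).
#'
#' @param counts A 2xK matrix of read counts, rows control then case.
#' @param utrLengths Tandem UTR lengths (the column scores).
#' @param minTotal Minimum table total (default 30 reads).
#' @return A list with `status` ("ok" or a skip reason), and for "ok" the
#'   reordered `table` and ascending `scores`.
#' @export
buildSwitchTable <- function(counts, utrLengths, minTotal = 30L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) == length(utrLengths))
  if (any(counts < 0)) stop("negative read counts")
  if (ncol(counts) < 2) return(list(status = "single_site"))
  o <- order(utrLengths)
  counts <- counts[, o, drop = FALSE]
  utrLengths <- utrLengths[o]
  if (any(rowSums(counts) == 0)) return(list(status = "not_coexpressed"))
  if (sum(counts) < minTotal) return(list(status = "low_count"))
  list(status = "ok", table = counts, scores = utrLengths)
}

#' Linear trend alternative to independence for a 2xK ordered table
#'
#' Computes the count-weighted Pearson correlation r between the row
#' scores (1 = control, 2 = case) and the column scores (the tandem UTR
#' lengths), the statistic `M2 = (n - 1) r^2`, and its upper-tail
#' chi-squared (df = 1) probability. A positive r means longer tandem
#' 3'UTRs in the case sample; negative, shorter. Tables with a degenerate
#' (zero-variance) margin give r = 0, p = 1.
#'
#' @param counts A 2xK matrix of non-negative counts (rows control, case).
#' @param colScores Ordered column scores, typically tandem UTR lengths.
#' @param rowScores Row scores; 1 and 2 by convention.
#' @return A list with `r`, `M2`, `p` and `n` (table total).
#' @export
linearTrendTest <- function(counts, colScores, rowScores = c(1, 2)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    stop("a switch table needs at least two tandem sites (columns)")
  stopifnot(nrow(counts) == length(rowScores),
            ncol(counts) == length(colScores))
  if (any(counts < 0)) stop("negative read counts")
  n <- sum(counts)
  if (n < 2) return(list(r = 0, M2 = 0, p = 1, n = n))
  w <- as.vector(counts)                       # column-major
  x <- rep(rowScores, times = ncol(counts))
  y <- rep(colScores, each = nrow(counts))
  sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2) - sx^2 / n
  syy <- sum(w * y^2) - sy^2 / n
  sxy <- sum(w * x * y) - sx * sy / n
  if (sxx <= 0 || syy <= 0) return(list(r = 0, M2 = 0, p = 1, n = n))
  r <- sxy / sqrt(sxx * syy)
  M2 <- (n - 1) * r^2
  list(r = r, M2 = M2, p = stats::pchisq(M2, df = 1, lower.tail = FALSE), n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a validated front end to
#' [stats::p.adjust()] with method "BH").
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, monotone in the p-value ranks, capped at 1.
#' @export
bhFDR <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify switch-test results
#'
#' A gene is called `lengthened` when q <= `fdrCut` and r >= `rCut`
#' (longer tandem 3'UTR in the case sample), `shortened` when q <=
#' `fdrCut` and r <= -`rCut`, and `ns` otherwise.
#'
#' @param r,q Vectors of correlations and BH-adjusted p-values.
#' @param fdrCut FDR cutoff (default 0.01).
#' @param rCut Minimum |r| (default 0.1).
#' @return Character vector of classes.
#' @export
classifySwitches <- function(r, q, fdrCut = 0.01, rCut = 0.1) {
  ifelse(!is.na(q) & q <= fdrCut & r >= rCut, "lengthened",
         ifelse(!is.na(q) & q <= fdrCut & r <= -rCut, "shortened", "ns"))
}

# shared core over a list of per-gene tables
.switchTestCore <- function(geneIds, tables, scoreList, fdrCut, rCut, minTotal) {
  nG <- length(geneIds)
  K <- integer(nG); n <- integer(nG)
  r <- rep(NA_real_, nG); M2 <- rep(NA_real_, nG); p <- rep(NA_real_, nG)
  skip <- rep(NA_character_, nG)
  for (i in seq_len(nG)) {
    bt <- buildSwitchTable(tables[[i]], scoreList[[i]], minTotal = minTotal)
    K[i] <- length(scoreList[[i]]); n[i] <- sum(tables[[i]])
    if (bt$status != "ok") { skip[i] <- bt$status; next }
    tt <- linearTrendTest(bt$table, bt$scores)
    r[i] <- tt$r; M2[i] <- tt$M2; p[i] <- tt$p
  }
  q <- rep(NA_real_, nG)
  tested <- is.na(skip)
  q[tested] <- bhFDR(p[tested])
  cls <- rep("ns", nG)
  cls[tested] <- classifySwitches(r[tested], q[tested], fdrCut, rCut)
  DataFrame(geneId = geneIds, K = K, n = n, r = r, M2 = M2, p = p, q = q,
            class = cls, skip = skip)
}

#' Test tandem 3'UTR switching between two samples
#'
#' For every gene with two or more tandem sites, builds the 2xK switch
#' table (control row first), applies the linear trend alternative to
#' independence, adjusts p-values by Benjamini-Hochberg across the tested
#' genes, and classifies each gene as lengthened / shortened / ns at the
#' FDR and |r| cutoffs.
#'
#' @param models A [TandemUTRSet-class] from [assignTandemSites()].
#' @param controlSample,caseSample Column names of the counts assay for
#'   the control (row score 1) and case (row score 2) sample.
#' @param fdrCut,rCut,minTotal Calling thresholds: FDR 0.01, |r| >= 0.1,
#'   table total >= 30 reads by default.
#' @return A [S4Vectors::DataFrame] with one row per gene: `geneId`, `K`,
#'   `n`, `r`, `M2`, `p`, `q`, `class`, `skip` (NA for tested genes).
#' @export
testSwitching <- function(models, controlSample, caseSample,
                          fdrCut = 0.01, rCut = 0.1, minTotal = 30L) {
  rd <- rowData(models)
  cnt <- assay(models, "counts")
  stopifnot(all(c(controlSample, caseSample) %in% colnames(cnt)))
  genes <- unique(rd$geneId)
  tables <- lapply(genes, function(g) {
    sel <- rd$geneId == g
    rbind(control = cnt[sel, controlSample], case = cnt[sel, caseSample])
  })
  scores <- lapply(genes, function(g) rd$utrLength[rd$geneId == g])
  .switchTestCore(genes, tables, scores, fdrCut, rCut, minTotal)
}

#' Test switching on plain per-gene count tables
#'
#' Same procedure as [testSwitching()] for data already in 2xK table form,
#' e.g. from [simulateSwitchTables()].
#'
#' @param tables List of 2xK count matrices (rows control, case).
#' @param utrLengths List of column-score vectors matching `tables`.
#' @param geneIds Optional gene identifiers.
#' @param fdrCut,rCut,minTotal As in [testSwitching()].
#' @return As [testSwitching()].
#' @export
testSwitchingTables <- function(tables, utrLengths, geneIds = NULL,
                                fdrCut = 0.01, rCut = 0.1, minTotal = 30L) {
  if (is.null(geneIds)) geneIds <- sprintf("gene%04d", seq_along(tables))
  .switchTestCore(geneIds, tables, utrLengths, fdrCut, rCut, minTotal)
}

#' Merge per-patient switching results
#'
#' The union contains every gene called in at least one patient, with the
#' calling patient's class; genes called with opposite signs in different
#' patients are flagged discordant (counted once in the union, excluded
#' from the intersection). The intersection contains the genes called in
#' all patients with the same sign.
#'
#' @param results Named list of per-patient [testSwitching()] results.
#' @return A list with `union` and `intersection` DataFrames (`geneId`,
#'   per-patient class columns, `class`, and `discordant` in the union).
#' @export
mergePatients <- function(results) {
  stopifnot(length(results) >= 2)
  if (is.null(names(results)))
    names(results) <- sprintf("patient%d", seq_along(results))
  sig <- lapply(results, function(df)
    stats::setNames(as.character(df$class), df$geneId))
  allGenes <- sort(unique(unlist(lapply(sig, function(s) names(s)[s != "ns"]))))
  if (length(allGenes) == 0) {
    empty <- DataFrame(geneId = character(0), class = character(0),
                       discordant = logical(0))
    return(list(union = empty, intersection = empty))
  }
  perPat <- sapply(sig, function(s) {
    cl <- s[allGenes]; cl[is.na(cl)] <- "ns"; cl
  })
  perPat <- matrix(perPat, nrow = length(allGenes),
                   dimnames = list(allGenes, names(results)))
  cls <- character(length(allGenes)); disc <- logical(length(allGenes))
  for (i in seq_along(allGenes)) {
    calls <- setdiff(unique(perPat[i, ]), "ns")
    disc[i] <- length(calls) > 1
    cls[i] <- if (disc[i]) "discordant" else calls[1]
  }
  un <- DataFrame(geneId = allGenes, perPat, class = cls, discordant = disc)
  inAll <- rowSums(perPat != "ns") == length(results) & !disc
  list(union = un, intersection = un[inAll, , drop = FALSE])
}
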