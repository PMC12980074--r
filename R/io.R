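# Readers/writers for the two delimited dialects the method touches:
# PLINK-style .eigenvec/.eigenval pairs and ancestry-profile tables.

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

#' Read a component-score matrix with its eigenvalues
#'
#' Reads sample scores on principal (or haplotype) components together with
#' the per-component eigenvalues. Two dialects are supported:
#' \describe{
#'   \item{\code{plink-eigenvec}}{PLINK \code{.eigenvec} output, whitespace
#'     or tab delimited, with an optional header line starting with
#'     \code{#}. With a family-ID column (header \code{#FID IID PC1 ...}, or
#'     headerless files whose second column is non-numeric) the sample ID is
#'     \code{FID_IID}; otherwise the first column is the sample ID.}
#'   \item{\code{generic-tsv}}{a delimited table with header
#'     \code{sample_id c1 ... cM}.}
#' }
#' The eigenvalue file holds one nonnegative number per line, in component
#' order. The number of eigenvalues must equal the number of score columns.
#'
#' @param scoresPath path to the score table (\code{.eigenvec} or TSV).
#' @param eigenvalPath path to the eigenvalue file (one value per line).
#' @param dialect \code{"plink-eigenvec"} (default) or \code{"generic-tsv"}.
#' @return A [ComponentMatrix-class]; file row order is preserved.
#' @examples
#' evec <- tempfile(fileext = ".eigenvec")
#' eval <- tempfile(fileext = ".eigenval")
#' writeLines(c("#FID IID PC1 PC2", "F1 A 0.1 0.2", "F1 B -0.1 0.4"), evec)
#' writeLines(c("4", "1"), eval)
#' cm <- readComponentMatrix(evec, eval)
#' sampleIDs(cm)  # "F1_A" "F1_B"
#' @export
readComponentMatrix <- function(scoresPath, eigenvalPath,
                                dialect = c("plink-eigenvec", "generic-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(scoresPath))
    stop("score file not found: ", scoresPath)
  if (!file.exists(eigenvalPath))
    stop("eigenvalue file not found: ", eigenvalPath)
  ev <- scan(eigenvalPath, what = double(), quiet = TRUE)
  if (!length(ev) || any(!is.finite(ev)) || any(ev < 0))
    stop("eigenvalue file must contain one nonnegative number per line: ",
         eigenvalPath)

  lines <- readLines(scoresPath)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty score file: ", scoresPath)

  if (dialect == "plink-eigenvec") {
    header <- startsWith(trimws(lines[1]), "#")
    colNames <- NULL
    if (header) {
      hf <- split_fields(sub("^\\s*#", "", lines[1]))
      lines <- lines[-1]
      hasFID <- toupper(hf[1]) == "FID"
      nID <- if (hasFID) 2L else 1L
      colNames <- hf[-seq_len(nID)]
    } else {
      # headerless PLINK: two leading ID columns iff the second field is
      # non-numeric
      f1 <- split_fields(lines[1])
      nID <- if (length(f1) >= 2 &&
                 is.na(suppressWarnings(as.numeric(f1[2])))) 2L else 1L
    }
    rows <- lapply(lines, split_fields)
    ncf <- lengths(rows)
    if (length(unique(ncf)) != 1L)
      stop("ragged score file: rows have differing field counts")
    nScore <- ncf[1] - nID
    if (nScore < 1L) stop("score file has no component columns")
    ids <- if (nID == 2L)
      vapply(rows, function(r) paste(r[1], r[2], sep = "_"), character(1))
    else vapply(rows, `[`, character(1), 1L)
    raw <- vapply(rows, function(r) r[-seq_len(nID)], character(nScore))
    scores <- matrix(suppressWarnings(as.numeric(raw)),
                     nrow = length(rows), ncol = nScore, byrow = TRUE)
    if (anyNA(scores)) {
      bad <- which(is.na(scores), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric score at row %d, component column %d",
                   bad[1], bad[2]))
    }
    if (!is.null(colNames) && length(colNames) == nScore)
      colnames(scores) <- colNames
    else colnames(scores) <- paste0("PC", seq_len(nScore))
  } else {
    tab <- utils::read.table(scoresPath, header = TRUE,
                             stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (ncol(tab) < 2L) stop("generic table needs an ID column plus scores")
    ids <- as.character(tab[[1]])
    num <- tab[-1]
    for (j in seq_along(num)) {
      v <- suppressWarnings(as.numeric(num[[j]]))
      if (anyNA(v))
        stop(sprintf("non-numeric score at row %d, component column %d",
                     which(is.na(v))[1], j))
      num[[j]] <- v
    }
    scores <- as.matrix(num)
  }

  if (anyDuplicated(ids))
    stop("duplicate sample IDs in score file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (ncol(scores) != length(ev))
    stop(sprintf(
      "score file has %d component columns but eigenvalue file has %d values",
      ncol(scores), length(ev)))
  rownames(scores) <- ids
  ComponentMatrix(scores, ev)
}

#' Read an ancestry-profile table
#'
#' Reads a delimited table whose header row gives the source-population
#' labels: \code{sample_id <pop1> ... <popS>}. Rows whose sum deviates from
#' 1 by at most 1e-3 (typical rounding of upstream profile estimates) are
#' renormalized with a warning; larger deviations and negative entries are
#' errors.
#'
#' @param path path to the delimited profile table.
#' @return A [ProfileMatrix-class].
#' @export
readProfileMatrix <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 3L)
    stop("profile table needs an ID column plus at least 2 population columns")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in profile file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pr <- as.matrix(tab[-1])
  if (!is.numeric(pr)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(pr), nrow(pr)))), arr.ind = TRUE)
    stop(sprintf("non-numeric proportion at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  }
  if (any(pr < 0))
    stop("negative ancestry proportion for sample ",
         ids[which(rowSums(pr < 0) > 0)[1]])
  rs <- rowSums(pr)
  off <- abs(rs - 1)
  if (any(off > 1e-3))
    stop("profile row sum outside [1 - 1e-3, 1 + 1e-3] for sample ",
         ids[which(off > 1e-3)[1]], sprintf(" (sum %.6g)", rs[off > 1e-3][1]))
  if (nrow(pr) > 0 && any(off > 1e-12)) {
    warning(sprintf("renormalized %d profile row(s) whose sums deviated from 1 by up to %.2g",
                    sum(off > 1e-12), max(off)))
    pr <- pr / rs
  }
  rownames(pr) <- ids
  ProfileMatrix(pr)
}

#' Write an ancestry-profile table
#'
#' Writes a tab-delimited table with header \code{sample_id} followed by the
#' population labels, proportions in fixed 6-decimal format. The file
#' round-trips through [readProfileMatrix()] to within 1e-6 per entry, and
#' repeated writes of the same object are byte-identical.
#'
#' @param profiles a [ProfileMatrix-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeProfileMatrix <- function(profiles, path) {
  stopifnot(is(profiles, "ProfileMatrix"))
  pr <- profiles@proportions
  labels <- colnames(pr)
  ids <- rownames(pr)
  if (any(grepl("\t", c(labels, ids))))
    stop("sample IDs and population labels must not contain tab characters")
  header <- paste(c("sample_id", labels), collapse = "\t")
  body <- if (nrow(pr)) {
    vapply(seq_len(nrow(pr)), function(i)
      paste(c(ids[i], sprintf("%.6f", pr[i, ])), collapse = "\t"),
      character(1))
  } else character(0)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
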