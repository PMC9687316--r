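#' Pairwise RMSD matrix of a pose ensemble
#'
#' Computes the symmetric matrix of root-mean-square deviations between all
#' frame pairs, in nanometres. With `fit = TRUE` (default) each pair is
#' optimally superposed first (Kabsch least squares), so rigid rotations and
#' translations do not contribute; with `fit = FALSE` raw coordinates are
#' compared. The default atom selection is all atoms, the convention used
#' when clustering rigid-body docking poses.
#'
#' @param ensemble a [PoseEnsemble-class] with at least two frames.
#' @param fit superpose each pair before measuring (default `TRUE`).
#' @param selection atom selection: `NULL` for all atoms, a chain-id
#'   character vector, a logical/integer vector over atoms, or a predicate
#'   `function(atom_table)`.
#' @return symmetric numeric matrix, nm, zero diagonal.
#' @seealso [gromosCluster()]
#' @export
pairwiseRMSD <- function(ensemble, fit = TRUE, selection = NULL) {
  stopifnot(is(ensemble, "PoseEnsemble"))
  n <- nFrames(ensemble)
  if (n < 2L) stop("pairwise RMSD needs at least 2 frames")
  idx <- resolve_selection(selection, atoms(ensemble), "selection")
  m <- matrix(0, n, n)
  frames <- lapply(seq_len(n), function(i)
    ensemble@coords[, , i][idx, , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- frames[[i]]
      b <- frames[[j]]
      if (fit) b <- kabsch_superpose(b, a)
      m[i, j] <- m[j, i] <- coord_rmsd(a, b) / 10  # Angstrom -> nm
    }
  }
  m
}

#' Daura/GROMOS clustering of an RMSD matrix
#'
#' The iterative neighbor-count algorithm used by `gmx cluster -method
#' gromos`: repeatedly take the pose with the most neighbors within the
#' cutoff (neighbor means RMSD `<=` cutoff, the GROMOS convention), emit
#' that pose and its neighbors as one cluster with the pose as center,
#' remove them, and repeat until no pose is left. When two remaining poses
#' have equal neighbor counts the lower pose index wins, which makes the
#' result deterministic. Clusters are returned largest first; groups of
#' equal-sized clusters are recorded so that a tie for "most populated" is
#' visible.
#'
#' @param matrix symmetric RMSD matrix in nm (e.g. from [pairwiseRMSD()]).
#' @param cutoff neighbor cutoff, nm; default 0.3.
#' @return a [ClusterResult-class].
#' @export
gromosCluster <- function(matrix, cutoff = 0.3) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("need a square RMSD matrix")
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8)))
    stop("RMSD matrix must be symmetric")
  if (any(matrix < 0)) stop("RMSD values must be >= 0")
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(matrix)
  adj <- matrix <= cutoff
  diag(adj) <- TRUE
  remaining <- rep(TRUE, n)
  cl <- list()
  while (any(remaining)) {
    live <- which(remaining)
    counts <- colSums(adj[live, live, drop = FALSE])
    center <- live[which.max(counts)]  # which.max takes the first maximum
    members <- live[adj[live, center]]
    cl[[length(cl) + 1L]] <- list(center = as.integer(center),
                                  members = as.integer(sort(members)))
    remaining[members] <- FALSE
  }
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  centers <- vapply(cl, `[[`, integer(1), "center")
  ord <- order(-sizes, centers)
  cl <- cl[ord]
  sizes <- sizes[ord]
  ties <- unname(lapply(
    split(seq_along(sizes), sizes)[table(sizes) > 1],
    as.integer))
  new("ClusterResult", clusters = cl, cutoff = cutoff, n = as.integer(n),
      ties = ties)
}

#' Representative pose of a clustering
#'
#' The center of the most populated cluster -- the single conformation used
#' downstream for interface analysis. When several clusters share the top
#' size, the one whose center has the smallest pose index is chosen and the
#' tie is reported via a warning (it is also stored in the
#' [ClusterResult-class] `ties` slot).
#'
#' @param result a [ClusterResult-class].
#' @param quiet suppress the tie warning.
#' @return integer pose index (1-based).
#' @export
representative <- function(result, quiet = FALSE) {
  stopifnot(is(result, "ClusterResult"))
  if (!length(result@clusters)) stop("empty clustering result")
  sizes <- clusterSizes(result)
  top <- which(sizes == sizes[1])
  centers <- vapply(result@clusters[top], `[[`, integer(1), "center")
  if (length(top) > 1L && !quiet)
    warning(sprintf(
      "%d equally populated clusters (%d members); choosing center %d",
      length(top), sizes[1], min(centers)))
  min(centers)
}

#' Summarize docked scores
#'
#' Docking-engine scores are inputs, never recomputed; the only score
#' arithmetic is the per-receptor average reported alongside docked
#' complexes. Reports round to one decimal, matching how such averages are
#' printed.
#'
#' @param scores numeric vector of docked scores (at least one).
#' @param digits decimals used in the rounded report value.
#' @return list with `mean` (full precision) and `report` (rounded).
#' @examples
#' summarizeScores(c(-670.7, -624.5, -722.1, -754.3, -464.0))$report
#' @export
summarizeScores <- function(scores, digits = 1) {
  scores <- as.numeric(scores)
  if (!length(scores) || anyNA(scores))
    stop("need at least one non-missing score")
  m <- mean(scores)
  list(mean = m, report = round(m, digits))
}

#' Read a per-pose score table
#'
#' Sidecar TSV with columns `pose_id` and `score` (extra grouping columns
#' such as `receptor`/`ligand` are kept).
#'
#' @param file path to a tab-separated file with a header.
#' @return `data.frame`.
#' @export
readScoreTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("pose_id", "score") %in% names(df)))
    stop("score table needs 'pose_id' and 'score' columns")
  df$score <- as.numeric(df$score)
  df
}
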