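#' Normalize a screening plate to its negative controls
#'
#' Divides every well's raw signal by the median of the plate's
#' negative-control (vehicle) wells, so negative controls map to ~1 and the
#' result is invariant to per-plate multiplicative scaling.
#'
#' @param plate data.frame with columns `plate_id`, `well_id`, `compound_id`
#'   (compound name, or `"POS"`/`"NEG"` for controls), `replicate`, `signal`.
#' @return the plate with an extra `normalized` column.
#' @export
normalize_plate <- function(plate) {
  stopifnot(all(c("plate_id", "well_id", "compound_id", "replicate", "signal")
                %in% names(plate)))
  neg <- plate$signal[plate$compound_id == "NEG"]
  if (length(neg) < 2L) stop("plate needs >= 2 negative-control wells")
  if (any(plate$signal < 0)) stop("raw signals must be non-negative")
  m <- median(neg)
  if (m <= 0) stop("negative-control median must be positive")
  plate$normalized <- plate$signal / m
  plate
}

#' Control-referenced z-score hit calling across a screen
#'
#' Normalizes every plate to its negative controls, averages each well's
#' normalized signal over the replicate plates (compounds and controls
#' alike, paired by plate and well), and scores each compound as
#' `z = (mean normalized signal - mu_neg) / sigma_neg`, with `mu_neg` and
#' `sigma_neg` estimated from the pooled replicate-averaged negative
#' controls — so compound statistics and the null reference are estimated on
#' the same (replicate-averaged) level. Hits are compounds with
#' `z < threshold`. Positive controls are summarized as an informational
#' Z'-style separation check, not used in the z-score.
#'
#' @param plates list of plate data.frames (or one combined data.frame); see
#'   [normalize_plate()] for required columns.
#' @param threshold hit threshold on the z-score (-2.12 by default).
#' @return object of class `hit_table`: data.frame with columns
#'   `compound_id`, `mean_normalized`, `z`, `is_hit`, plus attributes
#'   `mu_neg`, `sigma_neg`, `control_separation`.
#' @export
zscore_hits <- function(plates, threshold = -2.12) {
  if (is.data.frame(plates)) plates <- list(plates)
  combined <- do.call(rbind, plates)
  # one physical plate = one plate_id x replicate pair; normalize each
  physical <- split(combined, list(combined$plate_id, combined$replicate),
                    drop = TRUE)
  all <- do.call(rbind, lapply(physical, normalize_plate))
  ctrl <- all$compound_id %in% c("POS", "NEG")
  # replicate-average every well: compounds by id, controls by plate + well
  key <- ifelse(ctrl, paste(all$plate_id, all$well_id, all$compound_id),
                all$compound_id)
  avg <- tapply(all$normalized, key, mean)
  role <- tapply(all$compound_id, key, function(x) x[1])
  neg <- avg[role == "NEG"]
  pos <- avg[role == "POS"]
  if (length(neg) < 2L) stop("need >= 2 negative-control wells to estimate sigma")
  mu <- mean(neg)
  sigma <- sd(neg)
  if (sigma == 0) stop("negative-control sd is zero; z-scores undefined")
  cmp <- avg[!(role %in% c("POS", "NEG"))]
  z <- (cmp - mu) / sigma
  out <- data.frame(
    compound_id = names(cmp),
    mean_normalized = unname(cmp),
    z = unname(z),
    is_hit = unname(z < threshold),
    row.names = NULL
  )
  out <- out[order(out$z), ]
  rownames(out) <- NULL
  attr(out, "mu_neg") <- mu
  attr(out, "sigma_neg") <- sigma
  # Z'-factor-style separation between control distributions (QC only)
  if (length(pos) >= 2L) {
    attr(out, "control_separation") <-
      1 - 3 * (sigma + sd(pos)) / abs(mu - mean(pos))
  }
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Jaccard (Tanimoto) similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`; the corresponding distance `1 - similarity` is a
#' metric.
#'
#' @param a,b binary (0/1) vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a)
  b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0L) stop("Jaccard undefined: both fingerprints are all-zero")
  sum(a & b) / union
}

#' Pairwise Jaccard distance matrix of a fingerprint set
#'
#' @param fps binary matrix, compounds in rows (rownames are compound ids).
#' @return a `dist` object of Jaccard distances (1 - similarity).
#' @export
jaccard_distance <- function(fps) {
  fps <- as.matrix(fps)
  storage.mode(fps) <- "numeric"
  if (any(rowSums(fps) == 0)) stop("all-zero fingerprint: Jaccard undefined")
  inter <- tcrossprod(fps)
  ones <- rowSums(fps)
  union <- outer(ones, ones, `+`) - inter
  as.dist(1 - inter / union)
}

#' Cluster hit compounds by structural similarity
#'
#' Average-linkage hierarchical clustering on Jaccard distance, cut at
#' `cut_distance`. Clusters with two or more members are flagged as scaffold
#' families; singletons are reported separately.
#'
#' @param fps binary fingerprint matrix, compounds in rows.
#' @param cut_distance tree cut height in \[0, 1\].
#' @param method linkage method for [stats::hclust()] ("average").
#' @return list with `assignment` (named integer vector), `families` (list
#'   of member vectors, size >= 2), `singletons` (character vector), and the
#'   `hclust` tree.
#' @export
cluster_hits <- function(fps, cut_distance, method = "average") {
  fps <- as.matrix(fps)
  if (nrow(fps) < 2L) stop("clustering needs at least two compounds")
  tree <- hclust(jaccard_distance(fps), method = method)
  assignment <- cutree(tree, h = cut_distance)
  groups <- split(names(assignment), assignment)
  fam <- groups[lengths(groups) >= 2L]
  names(fam) <- NULL
  list(
    assignment = assignment,
    families = fam,
    singletons = unlist(groups[lengths(groups) == 1L], use.names = FALSE) %||% character(0),
    tree = tree
  )
}

#' Read screening plates from CSV
#'
#' Columns: `plate_id`, `well_id`, `compound_id` (or `POS`/`NEG`),
#' `replicate`, `signal`.
#'
#' @param path file path.
#' @return list of per-plate data.frames.
#' @export
read_plates <- function(path) {
  tab <- read.csv(path, colClasses = c(plate_id = "character",
                                       well_id = "character",
                                       compound_id = "character"))
  unname(split(tab, tab$plate_id))
}

#' Write screening plates as one CSV
#' @param plates list of plate data.frames.
#' @param path output file path.
#' @export
write_plates <- function(plates, path) {
  write.csv(do.call(rbind, plates), path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hit table as TSV
#' @param hits a `hit_table`.
#' @param path output file path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fingerprints from a TSV of bitstrings
#'
#' Two columns: `compound_id` and a fixed-length string of 0/1 characters.
#'
#' @param path file path.
#' @return binary matrix, compounds in rows.
#' @export
read_fingerprints <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  bits <- strsplit(tab[[2]], "")
  if (length(unique(lengths(bits))) != 1L) stop("fingerprints differ in length")
  m <- do.call(rbind, lapply(bits, as.integer))
  rownames(m) <- tab[[1]]
  m
}

#' Write fingerprints as a TSV of bitstrings
#' @param fps binary matrix, compounds in rows.
#' @param path output file path.
#' @export
write_fingerprints <- function(fps, path) {
  write.table(
    data.frame(compound_id = rownames(fps),
               fingerprint = apply(fps, 1, paste, collapse = "")),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
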