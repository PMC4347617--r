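#' Overlap score between a predicted cluster and a known complex
#'
#' \deqn{O(C, K) = \frac{|C \cap K|^2}{|C| \cdot |K|}.}
#' Symmetric, in \eqn{[0, 1]}, and equal to 1 exactly when the two sets
#' coincide. A predicted cluster is said to match a known complex when
#' \eqn{O(C, K) \ge \tau}; the conventional matching threshold for protein
#' complex validation is \eqn{\tau = 0.2}.
#'
#' @param c,k non-empty character vectors (vertex id sets).
#' @return a number in \eqn{[0, 1]}.
#' @export
overlap_score <- function(c, k) {
  c <- unique(as.character(c)); k <- unique(as.character(k))
  if (length(c) == 0L || length(k) == 0L) {
    stop("overlap_score requires non-empty sets")
  }
  length(intersect(c, k))^2 / (length(c) * length(k))
}

#' Match predicted clusters against a known-complex catalog
#'
#' Evaluates the clusters of size at least \code{min_size} as predicted
#' complexes. A predicted complex counts as a true positive (TP) when it
#' matches at least one known complex at overlap score
#' \eqn{O(C, K) \ge \tau}; it counts once no matter how many complexes it
#' matches. FN is the number of known complexes matched by no prediction,
#' and FP the number of evaluated predictions that match nothing. Then
#' \deqn{Sensitivity = \frac{TP}{TP + FN}, \quad
#'       Specificity = \frac{TP}{TP + FP},}
#' and the F-score is their harmonic mean (0 when both are 0).
#'
#' @param p a \code{pin_partition} whose clusters are the predicted
#'   complexes.
#' @param complexes a named list of character vectors (the known-complex
#'   catalog), e.g. from \code{\link{read_complex_catalog}}.
#' @param tau matching threshold, \eqn{0 < \tau \le 1}; default 0.2.
#' @param min_size smallest predicted cluster evaluated; default 3,
#'   matching the usual gold-standard filter.
#' @return a list of class \code{match_report}: counts \code{tp},
#'   \code{fp}, \code{fn}, \code{n_predicted}, \code{n_known},
#'   \code{perfect_matches}, rates \code{sensitivity}, \code{specificity},
#'   \code{f_score}, and \code{per_pair}, a data.frame of all nonzero
#'   overlap scores (columns \code{predicted}, \code{complex},
#'   \code{score}).
#' @export
complex_match_stats <- function(p, complexes, tau = 0.2, min_size = 3) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau > 1) {
    stop("`tau` must be a single number in (0, 1]")
  }
  if (min_size < 1) stop("`min_size` must be >= 1")
  if (length(complexes) == 0L) stop("empty complex catalog")
  if (is.null(names(complexes))) {
    names(complexes) <- sprintf("K%d", seq_along(complexes))
  }
  pred <- p$clusters[lengths(p$clusters) >= min_size]
  pred_id <- which(lengths(p$clusters) >= min_size)
  pairs <- list()
  pred_hit <- logical(length(pred))
  known_hit <- logical(length(complexes))
  perfect <- 0L
  for (i in seq_along(pred)) {
    for (j in seq_along(complexes)) {
      o <- overlap_score(pred[[i]], complexes[[j]])
      if (o > 0) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          predicted = pred_id[i], complex = names(complexes)[j], score = o)
      }
      if (o >= tau) {
        pred_hit[i] <- TRUE
        known_hit[j] <- TRUE
      }
    }
    if (length(complexes) &&
        any(vapply(complexes, function(k) setequal(pred[[i]], k),
                   logical(1)))) {
      perfect <- perfect + 1L
    }
  }
  tp <- sum(pred_hit)
  fp <- length(pred) - tp
  fn <- sum(!known_hit)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (sens + spec > 0) 2 * sens * spec / (sens + spec) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 n_predicted = length(pred), n_known = length(complexes),
                 perfect_matches = perfect,
                 sensitivity = sens, specificity = spec, f_score = f,
                 per_pair = if (length(pairs)) do.call(rbind, pairs)
                            else data.frame(predicted = integer(0),
                                            complex = character(0),
                                            score = numeric(0))),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(paste0("match_report: %d predicted vs %d known complexes\n",
                     "  TP %d  FP %d  FN %d  perfect %d\n",
                     "  sensitivity %.4f  specificity %.4f  F-score %.4f\n"),
              x$n_predicted, x$n_known, x$tp, x$fp, x$fn, x$perfect_matches,
              x$sensitivity, x$specificity, x$f_score))
  invisible(x)
}

#' Functional-category recall, precision and F-measure per module
#'
#' Scores each cluster of size at least \code{min_size} against a catalog
#' of functional categories. For a module \eqn{C} and category \eqn{F_i},
#' \deqn{Recall = \frac{|C \cap F_i|}{|F_i|}, \quad
#'       Precision = \frac{|C \cap F_i|}{|C|},}
#' with the F-measure their harmonic mean (0 when both are 0). Each module
#' is mapped to the category maximizing its F-measure (ties broken by
#' lexicographically smallest category id), and the overall accuracy is the
#' mean F-measure over evaluated modules.
#'
#' @param p a \code{pin_partition}.
#' @param annotations a named list of character vectors mapping category id
#'   to member proteins, e.g. from \code{\link{read_annotation_catalog}}.
#' @param min_size smallest module evaluated; default 3.
#' @return a list with \code{modules}, a data.frame (columns
#'   \code{cluster_id}, \code{size}, \code{category}, \code{recall},
#'   \code{precision}, \code{f_measure}), and \code{accuracy}, the mean
#'   F-measure (NA when no module qualifies).
#' @export
module_category_scores <- function(p, annotations, min_size = 3) {
  if (length(annotations) == 0L) stop("empty annotation catalog")
  if (min_size < 1) stop("`min_size` must be >= 1")
  if (is.null(names(annotations))) {
    names(annotations) <- sprintf("F%d", seq_along(annotations))
  }
  cat_ids <- sort(names(annotations))
  keep <- which(lengths(p$clusters) >= min_size)
  rows <- lapply(keep, function(i) {
    cl <- p$clusters[[i]]
    best <- data.frame(cluster_id = i, size = length(cl),
                       category = NA_character_, recall = 0,
                       precision = 0, f_measure = 0)
    for (cid in cat_ids) {             # sorted: lexicographic tie-break
      fi <- annotations[[cid]]
      inter <- length(intersect(cl, fi))
      rec <- inter / length(fi)
      prec <- inter / length(cl)
      f <- if (rec + prec > 0) 2 * rec * prec / (rec + prec) else 0
      if (f > best$f_measure ||
          (is.na(best$category) && f == best$f_measure)) {
        best$category <- cid
        best$recall <- rec; best$precision <- prec; best$f_measure <- f
      }
    }
    best
  })
  modules <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), size = integer(0),
               category = character(0), recall = numeric(0),
               precision = numeric(0), f_measure = numeric(0))
  list(modules = modules,
       accuracy = if (nrow(modules)) mean(modules$f_measure) else NA_real_)
}

#' Read a known-complex catalog
#'
#' Expects a flat TSV with columns \code{complex_id} and a
#' semicolon-joined member list (one complex per row), the shape of flat
#' exports of curated complex catalogs. Complexes with fewer than
#' \code{min_size} members after de-duplication are dropped, following the
#' usual gold-standard filter of keeping complexes of at least three
#' proteins.
#'
#' @param path file path.
#' @param min_size smallest complex retained; default 3.
#' @return a named list of character vectors.
#' @export
read_complex_catalog <- function(path, min_size = 3) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("complex_id", "members"),
                          colClasses = "character", comment.char = "#")
  members <- lapply(strsplit(df$members, ";", fixed = TRUE), unique)
  names(members) <- df$complex_id
  members[lengths(members) >= min_size]
}

#' @rdname read_complex_catalog
#' @param complexes a named list of character vectors.
#' @export
write_complex_catalog <- function(complexes, path) {
  lines <- sprintf("%s\t%s", names(complexes),
                   vapply(complexes, paste, character(1), collapse = ";"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-to-category annotation table
#'
#' Expects a TSV with columns \code{protein_id}, \code{category_id}, one
#' pair per row; a protein may appear under several categories.
#'
#' @param path file path.
#' @return a named list mapping category id to character vector of
#'   proteins.
#' @export
read_annotation_catalog <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("protein_id", "category_id"),
                          colClasses = "character", comment.char = "#")
  lapply(split(df$protein_id, df$category_id), unique)
}

#' @rdname read_annotation_catalog
#' @param annotations a named list of character vectors.
#' @export
write_annotation_catalog <- function(annotations, path) {
  df <- data.frame(
    protein_id = unlist(annotations, use.names = FALSE),
    category_id = rep(names(annotations), lengths(annotations)))
  utils::write.table(df[order(df$category_id, df$protein_id), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
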