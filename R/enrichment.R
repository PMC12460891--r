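#' @title Over-representation enrichment
#' @description Hypergeometric over-representation testing of feature sets
#'   (tendencies, concordance types, presence sets) against gene -> domain or
#'   gene -> term annotation maps, with BH correction over tested terms.
#' @name enrichment
NULL

#' Read an annotation map
#'
#' Two formats: two-column tab-separated (`term_id`, `feature_id`, optional
#' third column term name), or GMT (`term_id`, description, then members).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gmt"`.
#' @return A named list of character vectors (class `AnnotationMap`): term id
#'   -> member feature ids. Term names, when given, in `attr(, "term_names")`.
#' @export
read_annotation_map <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    terms <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(terms) <- vapply(parts, `[`, character(1), 1)
    nm <- vapply(parts, `[`, character(1), 2)
  } else {
    df <- utils::read.delim(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    terms <- lapply(split(df[[2]], df[[1]]), unique)
    nm <- if (ncol(df) >= 3) {
      vapply(split(df[[3]], df[[1]]), `[`, character(1), 1)
    } else NULL
  }
  annotation_map(terms, term_names = nm)
}

#' Construct an annotation map
#'
#' @param terms Named list: term id -> character vector of feature ids.
#' @param term_names Optional named character vector of display names.
#' @return An `AnnotationMap`.
#' @export
annotation_map <- function(terms, term_names = NULL) {
  if (is.null(names(terms)) || any(names(terms) == "")) {
    stop("every term needs an id", call. = FALSE)
  }
  sizes <- vapply(terms, length, integer(1))
  if (any(sizes == 0)) {
    stop("empty term set(s): ",
         paste(names(terms)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  structure(lapply(terms, unique), term_names = term_names,
            class = "AnnotationMap")
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing a foreground of size `n`
#' from a background of `N` features of which `K` carry the term, the chance
#' of seeing `k` or more term members. Computed stably through
#' [stats::phyper]'s log-space machinery.
#'
#' @param k Hits in the foreground.
#' @param K Term size within the background.
#' @param n Foreground size.
#' @param N Background size.
#' @return The upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  vals <- c(k, K, n, N)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need K <= N, n <= N, k <= min(K, n)",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation test of a foreground set
#'
#' One hypergeometric upper-tail test per term whose background-restricted
#' size lies within `[min_term_size, max_term_size]`; BH q-values over the
#' tested terms only; deterministic ordering by p then term id.
#'
#' @param foreground Character vector of feature ids (must be a subset of
#'   `background`).
#' @param background Character vector: the tested universe (conventionally all
#'   features quantified in the relevant matrix).
#' @param ann An [annotation_map()]. Features outside the background are
#'   ignored (count reported in `attr(, "ignored_features")`).
#' @param min_term_size,max_term_size Term size bounds after background
#'   restriction (defaults 3 and 500).
#' @return Data frame: `term_id`, `k`, `K`, `n`, `N`, `fold_enrichment`
#'   (`(k/n)/(K/N)`), `p_value`, `q_value`.
#' @export
enrich <- function(foreground, background, ann, min_term_size = 3,
                   max_term_size = 500) {
  stopifnot(inherits(ann, "AnnotationMap"))
  foreground <- unique(foreground)
  background <- unique(background)
  extra <- setdiff(foreground, background)
  if (length(extra)) {
    stop("foreground features absent from background: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ...", call. = FALSE)
  }
  if (!length(background)) stop("empty background", call. = FALSE)
  N <- length(background)
  n <- length(foreground)
  ignored <- 0L
  rows <- lapply(names(ann), function(tid) {
    members <- unclass(ann)[[tid]]
    ignored <<- ignored + length(setdiff(members, background))
    members <- intersect(members, background)
    K <- length(members)
    if (K < min_term_size || K > max_term_size) return(NULL)
    k <- length(intersect(members, foreground))
    fold <- if (n > 0 && K > 0) (k / n) / (K / N) else 0
    data.frame(term_id = tid, k = k, K = K, n = n, N = N,
               fold_enrichment = fold,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      q_value = numeric(0))
    attr(out, "ignored_features") <- ignored
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ignored_features") <- ignored
  out
}
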