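#' Create a feature record
#'
#' One repository row: the first-order features of one case's ROI on one
#' parametric map, with its group label.
#'
#' @param case_id pseudonymous, non-empty case identifier.
#' @param group `"malignant"`, `"benign"`, or `"unknown"`.
#' @param map_kind the [parametric_map()] kind the features were computed on.
#' @param features a [compute_features()] result or named numeric list.
#' @param diagnosis free-text diagnosis (optional).
#' @param nbins histogram bin count used for the entropy feature.
#' @param created timestamp string (defaults to now, UTC).
#' @return A list of class `feature_record`.
#' @export
feature_record <- function(case_id, group, map_kind, features,
                           diagnosis = "", nbins = 256L,
                           created = format(Sys.time(), tz = "UTC",
                                            "%Y-%m-%dT%H:%M:%SZ")) {
  if (!nzchar(case_id)) stop("case_id must be non-empty", call. = FALSE)
  group <- match.arg(group, c("malignant", "benign", "unknown"))
  map_kind <- match.arg(map_kind, map_kinds())
  feats <- lapply(unclass(features), as.numeric)
  if (!all(c("mean", "median") %in% names(feats)))
    stop("features must at least contain 'mean' and 'median'", call. = FALSE)
  structure(list(case_id = as.character(case_id), group = group,
                 diagnosis = as.character(diagnosis), map_kind = map_kind,
                 features = feats, nbins = as.integer(nbins),
                 created = created, schema_version = 1L),
            class = "feature_record")
}

#' Feature repository
#'
#' A self-archiving, append-only store of [feature_record()]s, persisted as
#' JSON lines (one record per line) so that archives diff cleanly and need
#' no database server.
#'
#' @param records optional list of `feature_record`s to start from.
#' @return A list of class `feature_repository`.
#' @export
feature_repository <- function(records = list()) {
  structure(list(records = records), class = "feature_repository")
}

#' @export
print.feature_repository <- function(x, ...) {
  groups <- vapply(x$records, `[[`, "", "group")
  cat(sprintf("<feature_repository> %d records", length(x$records)))
  if (length(groups))
    cat(" (", paste(sprintf("%s: %d", names(table(groups)), table(groups)),
                    collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Add a record to a repository
#'
#' @param repo a [feature_repository()].
#' @param record a [feature_record()].
#' @param overwrite replace an existing record with the same
#'   `case_id` + `map_kind` instead of erroring.
#' @return The updated repository.
#' @export
add_record <- function(repo, record, overwrite = FALSE) {
  stopifnot(inherits(repo, "feature_repository"),
            inherits(record, "feature_record"))
  key <- function(r) paste(r$case_id, r$map_kind, sep = "\r")
  keys <- vapply(repo$records, key, "")
  hit <- which(keys == key(record))
  if (length(hit)) {
    if (!overwrite)
      stop("duplicate record for case '", record$case_id, "' on map ",
           record$map_kind, " (use overwrite = TRUE to replace)",
           call. = FALSE)
    repo$records[[hit]] <- record
  } else {
    repo$records[[length(repo$records) + 1L]] <- record
  }
  repo
}

#' Query records by group and/or map kind
#'
#' @param repo a [feature_repository()].
#' @param group,map_kind optional filters; `NULL` = no filter.
#' @return List of matching records, in insertion order.
#' @export
query_records <- function(repo, group = NULL, map_kind = NULL) {
  stopifnot(inherits(repo, "feature_repository"))
  keep <- vapply(repo$records, function(r) {
    (is.null(group) || r$group == group) &&
      (is.null(map_kind) || r$map_kind == map_kind)
  }, TRUE)
  repo$records[keep]
}

#' Save / load a repository as JSON lines
#'
#' @param repo a [feature_repository()].
#' @param path `.jsonl` file, one record per line.
#' @return `save_repository()` returns `path` invisibly;
#'   `load_repository()` returns a `feature_repository`.
#' @export
save_repository <- function(repo, path) {
  stopifnot(inherits(repo, "feature_repository"))
  lines <- vapply(repo$records, function(r)
    jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA, null = "null"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_repository
#' @export
load_repository <- function(path) {
  if (!file.exists(path)) stop("no repository at ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  records <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    feature_record(r$case_id, r$group, r$map_kind, as.list(r$features),
                   diagnosis = r$diagnosis %||% "", nbins = r$nbins %||% 256L,
                   created = r$created %||% "")
  })
  feature_repository(records)
}

features_matrix <- function(records, features = NULL) {
  stopifnot(length(records) > 0)
  features <- features %||%
    Reduce(intersect, lapply(records, function(r) names(r$features)))
  m <- t(vapply(records, function(r)
    unlist(r$features[features], use.names = FALSE),
    numeric(length(features))))
  colnames(m) <- features
  rownames(m) <- vapply(records, `[[`, "", "case_id")
  m
}

#' Per-feature group statistics
#'
#' Mean and SD of every feature over the records of one tumor group — the
#' training model of the threshold classifier and the reference band of the
#' case-vs-group report. Population SD (divide by n) by default, matching
#' the moment convention of the feature extractor.
#'
#' @param repo a [feature_repository()].
#' @param group group label to summarize.
#' @param map_kind map kind to summarize.
#' @param sample_sd use the n-1 denominator instead.
#' @return A list of class `group_stats`: `group`, `map_kind`, `n`, and a
#'   data frame `stats` with columns `feature`, `mean`, `sd`.
#' @export
group_summary <- function(repo, group, map_kind, sample_sd = FALSE) {
  recs <- query_records(repo, group = group, map_kind = map_kind)
  if (length(recs) < 2L)
    stop("group summary needs >= 2 records (", group, "/", map_kind,
         " has ", length(recs), ")", call. = FALSE)
  m <- features_matrix(recs)
  mu <- colMeans(m)
  denom <- if (sample_sd) nrow(m) - 1L else nrow(m)
  sdv <- sqrt(colSums(sweep(m, 2, mu)^2) / denom)
  structure(list(group = group, map_kind = map_kind, n = length(recs),
                 stats = data.frame(feature = colnames(m), mean = mu,
                                    sd = sdv, row.names = NULL)),
            class = "group_stats")
}

#' Compare an index case against the repository groups
#'
#' For every feature and each tumor group: the group mean and SD band, the
#' index case's value, its z-score `(value - mean) / SD`, and whether it
#' lies within one SD of the group mean — the information behind the
#' case-vs-group decision-support display.
#'
#' @param repo a [feature_repository()].
#' @param index_features a [compute_features()] result or named numeric
#'   list for the case under review.
#' @param map_kind map kind to compare on.
#' @param features features to report; defaults to all shared ones.
#' @return A data frame with columns `feature`, `group`, `n`, `mean`, `sd`,
#'   `value`, `z`, `within_1sd` (`z` is `NA` where the group SD is 0).
#' @export
compare_case <- function(repo, index_features, map_kind, features = NULL) {
  fv <- lapply(unclass(index_features), as.numeric)
  out <- list()
  for (g in c("malignant", "benign")) {
    gs <- group_summary(repo, g, map_kind)
    st <- gs$stats
    if (!is.null(features)) st <- st[st$feature %in% features, ]
    st <- st[st$feature %in% names(fv), ]
    val <- unlist(fv[st$feature], use.names = FALSE)
    z <- ifelse(st$sd > 0, (val - st$mean) / st$sd, NA_real_)
    out[[g]] <- data.frame(feature = st$feature, group = g, n = gs$n,
                           mean = st$mean, sd = st$sd, value = val, z = z,
                           within_1sd = ifelse(st$sd > 0, abs(z) <= 1, NA))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
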