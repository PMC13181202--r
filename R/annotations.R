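#' Consensus malignancy label from radiologist ratings
#'
#' Each reader scores a nodule 1..5. The aggregate grade (mean by default,
#' the common LIDC convention; median available) is compared to 3: above 3 is
#' malignant, below 3 benign, exactly 3 is an uncertain nodule and excluded
#' from the classification dataset.
#'
#' @param ratings integer vector of per-reader scores in 1..5.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return one of `"benign"`, `"malignant"`, `"excluded"`.
#' @export
assign_label <- function(ratings, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(ratings) < 1L) stop("ratings must be nonempty", call. = FALSE)
  if (any(is.na(ratings)) || any(ratings < 1 | ratings > 5))
    stop("ratings must all lie in 1..5", call. = FALSE)
  g <- if (aggregate == "mean") mean(ratings) else stats::median(ratings)
  if (g > 3) "malignant" else if (g < 3) "benign" else "excluded"
}

.parse_ratings_field <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(r) as.integer(r[nzchar(r)]))
}

# Union-find merge of annotations of the same series whose centers lie within
# half the (larger) diameter of each other. Ratings are concatenated, centers
# averaged, the diameter kept at its maximum.
.merge_annotations <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, length.out = n - i)) {
    if (df$seriesuid[i] != df$seriesuid[j]) next
    d <- sqrt((df$coordX[i] - df$coordX[j])^2 +
              (df$coordY[i] - df$coordY[j])^2 +
              (df$coordZ[i] - df$coordZ[j])^2)
    if (d < max(df$diameter_mm[i], df$diameter_mm[j]) / 2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), root), function(idx) {
    data.frame(seriesuid = df$seriesuid[idx[1L]],
               coordX = mean(df$coordX[idx]),
               coordY = mean(df$coordY[idx]),
               coordZ = mean(df$coordZ[idx]),
               diameter_mm = max(df$diameter_mm[idx]),
               ratings = I(list(unlist(df$ratings[idx]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Parse LUNA16-dialect nodule annotations
#'
#' Reads an annotations CSV (header `seriesuid,coordX,coordY,coordZ,
#' diameter_mm`, world-mm coordinates), optionally augmented with per-reader
#' malignancy scores, merges duplicate entries referring to the same physical
#' nodule (same series, centers within half a diameter), and drops nodules
#' read by fewer than `min_readers` radiologists.
#'
#' Ratings can come from (a) an extra `ratings` column holding
#' semicolon-separated scores (the dialect this package's phantom generator
#' writes), or (b) a sidecar CSV (`seriesuid,coordX,coordY,coordZ,rating`, one
#' row per reader) whose rows are attached to the nearest annotation of the
#' same series within half its diameter. When no rating source is present the
#' annotations pass through unlabelled and the reader filter does not apply.
#'
#' @param source path to the annotations CSV, or an equivalent data.frame.
#' @param ratings optional sidecar CSV path or data.frame as described above.
#' @param min_readers consensus threshold; nodules with fewer readers are
#'   dropped (default 3).
#' @param merge merge duplicate entries before filtering (default TRUE).
#' @return data.frame with columns `seriesuid, coordX, coordY, coordZ,
#'   diameter_mm, ratings` (list column), `reader_count`.
#' @export
parse_annotations <- function(source, ratings = NULL, min_readers = 3L, merge = TRUE) {
  df <- if (is.character(source)) {
    if (!file.exists(source)) stop("no such file: ", source, call. = FALSE)
    read.csv(source, stringsAsFactors = FALSE)
  } else as.data.frame(source, stringsAsFactors = FALSE)
  need <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation source lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cl in c("coordX", "coordY", "coordZ", "diameter_mm")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v) & !is.na(df[[cl]])))
      stop("malformed numeric value in column ", cl, ", row ",
           which(is.na(v) & !is.na(df[[cl]]))[1L], call. = FALSE)
    df[[cl]] <- v
  }
  if (any(df$diameter_mm <= 0))
    stop("diameter_mm must be positive (row ",
         which(df$diameter_mm <= 0)[1L], ")", call. = FALSE)

  has_ratings <- FALSE
  if ("ratings" %in% names(df)) {
    df$ratings <- I(.parse_ratings_field(df$ratings))
    has_ratings <- TRUE
  } else {
    df$ratings <- I(vector("list", nrow(df)))
  }
  if (!is.null(ratings)) {
    rs <- if (is.character(ratings)) read.csv(ratings, stringsAsFactors = FALSE)
          else as.data.frame(ratings, stringsAsFactors = FALSE)
    if (!all(c("seriesuid", "coordX", "coordY", "coordZ", "rating") %in% names(rs)))
      stop("ratings sidecar needs columns seriesuid,coordX,coordY,coordZ,rating",
           call. = FALSE)
    for (i in seq_len(nrow(rs))) {
      cand <- which(df$seriesuid == rs$seriesuid[i])
      if (!length(cand)) next
      d <- sqrt((df$coordX[cand] - rs$coordX[i])^2 +
                (df$coordY[cand] - rs$coordY[i])^2 +
                (df$coordZ[cand] - rs$coordZ[i])^2)
      j <- cand[which.min(d)]
      if (min(d) <= df$diameter_mm[j] / 2)
        df$ratings[[j]] <- c(df$ratings[[j]], as.integer(rs$rating[i]))
    }
    has_ratings <- TRUE
  }
  bad <- vapply(df$ratings, function(r) length(r) && any(r < 1 | r > 5), logical(1))
  if (any(bad))
    stop("rating outside 1..5 for seriesuid ", df$seriesuid[which(bad)[1L]],
         call. = FALSE)

  if (merge && nrow(df) > 1L) df <- .merge_annotations(df)
  df$reader_count <- vapply(df$ratings, length, integer(1))
  if (has_ratings) df <- df[df$reader_count >= min_readers, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Parse an LIDC-style XML reading session document
#'
#' Extracts, for every reading session and every nodule read in it, the
#' malignancy score and the centroid of the drawn contours. Rows from
#' different readers describing the same physical nodule are merged by
#' [parse_annotations()]'s proximity rule when fed back through it.
#'
#' @param path path to the XML document.
#' @param diameter_mm fallback nodule diameter used for reader-row grouping
#'   when contours span a single point (default 5).
#' @return data.frame with one row per (reader, nodule): `seriesuid, coordX,
#'   coordY, coordZ, diameter_mm, rating`.
#' @export
parse_lidc_xml <- function(path, diameter_mm = 5) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  uid <- xml2::xml_text(xml2::xml_find_first(doc, ".//SeriesInstanceUid"))
  if (is.na(uid) || !nzchar(uid)) uid <- "unknown-series"
  sessions <- xml2::xml_find_all(doc, ".//readingSession")
  rows <- list()
  for (s in sessions) {
    for (nod in xml2::xml_find_all(s, ".//unblindedReadNodule")) {
      mal <- xml2::xml_text(xml2::xml_find_first(nod, ".//characteristics/malignancy"))
      if (is.na(mal)) next
      xs <- as.numeric(xml2::xml_text(xml2::xml_find_all(nod, ".//edgeMap/xCoord")))
      ys <- as.numeric(xml2::xml_text(xml2::xml_find_all(nod, ".//edgeMap/yCoord")))
      zs <- as.numeric(xml2::xml_text(xml2::xml_find_all(nod, ".//roi/imageZposition")))
      if (!length(xs) || !length(ys) || !length(zs))
        stop("malformed unblindedReadNodule without contour in ", path, call. = FALSE)
      ex <- if (length(xs) > 1) max(dist(cbind(xs, ys))) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        seriesuid = uid, coordX = mean(xs), coordY = mean(ys), coordZ = mean(zs),
        diameter_mm = max(ex, diameter_mm), rating = as.integer(mal),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seriesuid = character(), coordX = numeric(),
                      coordY = numeric(), coordZ = numeric(),
                      diameter_mm = numeric(), rating = integer()))
  do.call(rbind, rows)
}
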