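#' Stratified validation sample
#'
#' Draws `n_per_class` pixels uniformly without replacement from each
#' *mapped* class of a label raster (stratification over map classes, so
#' the confusion matrix's column totals equal `n_per_class`). Classes with
#' fewer pixels contribute all of them, with a warning.
#'
#' @param labels an `lulc_labels` map.
#' @param n_per_class points per mapped class (the framework uses 1050).
#' @param seed integer seed; identical seeds give identical point sets.
#' @return A `sample_points` data.frame whose `class_id` is the *mapped*
#'   class at each point.
#' @export
stratified_sample <- function(labels, n_per_class, seed = 1L) {
  v <- labels$values
  if (all(is.na(v))) stop("empty map", call. = FALSE)
  cells <- which(!is.na(v))
  cls <- v[cells]
  rng <- local({
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    lapply(split(cells, cls), function(idx) {
      if (length(idx) <= n_per_class) {
        warning("class with fewer than ", n_per_class,
                " pixels: all taken", call. = FALSE)
        idx
      } else sample(idx, n_per_class)
    })
  })
  picked <- unlist(rng, use.names = FALSE)
  nr <- labels$grid$n_rows
  sample_points_df(row = (picked - 1L) %% nr,
                   col = (picked - 1L) %/% nr,
                   class_id = v[picked], level = labels$level,
                   year = NA_integer_, provenance = "interpreted")
}

#' Confusion matrix
#'
#' Square count matrix of reference vs mapped labels: rows are the
#' reference class, columns the mapped class, following the layout of
#' printed validation tables.
#'
#' @param ref,pred equal-length vectors of reference and mapped class ids.
#' @param classes class ids fixing the matrix order; defaults to the sorted
#'   union.
#' @param level taxonomy level, carried as an attribute.
#' @param class_names optional display names for dimnames.
#' @return An object of class `lulc_confusion` (an integer matrix with
#'   attributes `classes` and `level`).
#' @export
confusion <- function(ref, pred, classes = NULL, level = NA_integer_,
                      class_names = NULL) {
  if (length(ref) != length(pred))
    stop("ref and pred must have equal length", call. = FALSE)
  classes <- classes %||% sort(unique(c(ref, pred)))
  if (!all(c(ref, pred) %in% classes))
    stop("label outside the class set", call. = FALSE)
  f <- function(x) factor(x, levels = classes)
  m <- unclass(table(reference = f(ref), map = f(pred)))
  storage.mode(m) <- "integer"
  if (!is.null(class_names)) dimnames(m) <- list(reference = class_names,
                                                 map = class_names)
  structure(m, classes = classes, level = level,
            class = c("lulc_confusion", class(m)))
}

#' @export
print.lulc_confusion <- function(x, ...) {
  cat(sprintf("<lulc_confusion> %d classes, %d points\n", nrow(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Accuracy metrics from a confusion matrix
#'
#' The full stratified-validation metric suite. With rows = reference and
#' columns = map:
#' overall accuracy `OA = 100 * trace / total`;
#' producer accuracy `PA_k = 100 * diag_k / rowsum_k` (1 - omission);
#' user accuracy `UA_k = 100 * diag_k / colsum_k` (1 - commission);
#' `F1_k` the harmonic mean of PA and UA on the 0-1 scale;
#' `SEM_k = 100 * sqrt(ua (1 - ua) / colsum_k)`, the binomial standard
#' error of UA at the mapped-class sample size;
#' kappa `KC = 100 * (p_o - p_e) / (1 - p_e)` with
#' `p_e = sum(rowsum_k * colsum_k) / total^2`;
#' and the 95% binomial half-width of OA,
#' `100 * 1.96 * sqrt(oa (1 - oa) / total)`.
#' Divisions by zero yield `NA`, never 0.
#'
#' @param cm an `lulc_confusion` (any square count matrix accepted).
#' @return An object of class `lulc_metrics`: list with `per_class` (a
#'   data.frame of `class`, `PA`, `UA`, `F1`, `SEM`) and scalars `OA`,
#'   `KC`, `OA_ci95`, `n`.
#' @export
accuracy_metrics <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m); dg <- diag(m)
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  pa <- 100 * safe_div(dg, rs)
  ua <- 100 * safe_div(dg, cs)
  f1 <- 2 * (pa / 100) * (ua / 100) / ((pa + ua) / 100)
  f1[!is.na(pa + ua) & pa + ua == 0] <- NA_real_
  sem <- 100 * sqrt(safe_div((ua / 100) * (1 - ua / 100), cs))
  oa <- sum(dg) / total
  pe <- sum(rs * cs) / total^2
  kc <- if (pe < 1) 100 * (oa - pe) / (1 - pe) else NA_real_
  structure(
    list(per_class = data.frame(
           class = colnames(m) %||% attr(cm, "classes") %||% seq_len(nrow(m)),
           PA = pa, UA = ua, F1 = f1, SEM = sem, row.names = NULL),
         OA = 100 * oa, KC = kc,
         OA_ci95 = 100 * 1.96 * sqrt(oa * (1 - oa) / total),
         n = total),
    class = "lulc_metrics")
}

#' @export
print.lulc_metrics <- function(x, digits = 1, ...) {
  cat(sprintf("Overall accuracy: %.1f%% (+/- %.1f), kappa: %.1f, n = %d\n",
              x$OA, x$OA_ci95, x$KC, x$n))
  df <- x$per_class
  df$PA <- round(df$PA, digits); df$UA <- round(df$UA, digits)
  df$F1 <- round(df$F1, 2); df$SEM <- round(df$SEM, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Merge level-2 results to level 1
#'
#' Aggregates a level-2 confusion matrix (or label raster) by each class's
#' level-1 parent. Counts are conserved; confusion between sibling classes
#' becomes diagonal agreement, so overall accuracy can only rise.
#'
#' @param x an `lulc_confusion` or `lulc_labels` at level 2.
#' @param taxonomy an [lulc_taxonomy()].
#' @return The same type of object at level 1.
#' @export
merge_to_level1 <- function(x, taxonomy) {
  if (inherits(x, "lulc_labels")) {
    v <- level1_parent(taxonomy, as.vector(x$values))
    return(label_raster(matrix(as.integer(v), x$grid$n_rows, x$grid$n_cols),
                        x$grid, level = 1L))
  }
  stopifnot(inherits(x, "lulc_confusion"))
  classes <- attr(x, "classes")
  parents <- level1_parent(taxonomy, classes)
  l1 <- sort(unique(taxonomy$level1$id))
  f <- factor(parents, levels = l1)
  m <- rowsum(unclass(x), f)
  m <- t(rowsum(t(m), f))
  storage.mode(m) <- "integer"
  nm <- taxonomy$level1$name[match(l1, taxonomy$level1$id)]
  dimnames(m) <- list(reference = nm, map = nm)
  structure(m, classes = l1, level = 1L,
            class = c("lulc_confusion", "matrix", "array"))
}

#' Bundled nationwide validation confusion matrices
#'
#' The 2020 stratified-validation confusion matrices (1050 points per
#' mapped class) of a published nationwide annual land-cover mapping of
#' Vietnam, at both taxonomy levels. They serve as worked examples and as
#' regression fixtures for the metric suite.
#'
#' @param level 1 (10 classes) or 2 (18 classes).
#' @return An `lulc_confusion`.
#' @export
vietnam2020_confusion <- function(level = 1L) {
  stopifnot(level %in% c(1L, 2L))
  path <- system.file("extdata",
                      sprintf("vn2020_level%d_confusion.csv", level),
                      package = "annualcover", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("reference", "map")
  tax <- default_taxonomy()
  ids <- resolve_class(tax, rownames(m), level)
  structure(m, classes = ids, level = as.integer(level),
            class = c("lulc_confusion", "matrix", "array"))
}

#' Write a confusion matrix with its metrics as CSV
#'
#' Mirrors the printed validation tables: the count matrix with class
#' headers, followed by PA/UA/SEM/F1 rows and an OA/KC footer.
#'
#' @param cm an `lulc_confusion`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  met <- accuracy_metrics(cm)
  m <- unclass(cm)
  out <- rbind(as.data.frame(m),
               PA = round(met$per_class$PA, 1),
               UA = round(met$per_class$UA, 1),
               SEM = round(met$per_class$SEM, 1),
               F1 = round(met$per_class$F1, 2))
  utils::write.csv(out, path)
  cat(sprintf("# OA,%.1f\n# KC,%.1f\n# OA_ci95,%.1f\n",
              met$OA, met$KC, met$OA_ci95),
      file = path, append = TRUE)
  invisible(path)
}
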