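#' Construct a BagCohort
#'
#' @param bags named list of numeric matrices, one per patient; rows are
#'   instances (patches), columns are features. All bags must share the same
#'   number of columns.
#' @param survival data.frame with columns \code{bag_id}, \code{time} (> 0),
#'   \code{event} (0/1). Rows are matched to \code{bags} by \code{bag_id}.
#' @return a [BagCohort-class].
#' @examples
#' b <- list(p1 = matrix(rnorm(40), 10), p2 = matrix(rnorm(32), 8))
#' surv <- data.frame(bag_id = c("p1", "p2"), time = c(12, 30), event = c(1, 0))
#' BagCohort(b, surv)
#' @export
BagCohort <- function(bags, survival) {
  if (is.null(names(bags)))
    stop("'bags' must be a named list keyed by bag_id")
  survival$bag_id <- as.character(survival$bag_id)
  if (!setequal(survival$bag_id, names(bags)))
    stop("survival bag_ids must match names(bags)")
  survival <- survival[match(names(bags), survival$bag_id), , drop = FALSE]
  rownames(survival) <- NULL
  bags <- lapply(bags, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  new("BagCohort", bags = bags,
      survival = survival[, c("bag_id", "time", "event")])
}

#' Accessors for BagCohort
#'
#' @param x a [BagCohort-class].
#' @name BagCohort-accessors
#' @return \code{bagIds}: character vector of bag identifiers;
#'   \code{bags}: the named list of feature matrices;
#'   \code{survivalData}: data.frame of \code{bag_id}, \code{time},
#'   \code{event}; \code{featureDim}: the common number of feature columns;
#'   \code{nBags}: number of bags; \code{bagSizes}: named integer vector of
#'   instances per bag.
NULL

#' @rdname BagCohort-accessors
#' @export
setMethod("bagIds", "BagCohort", function(x) names(x@bags))

#' @rdname BagCohort-accessors
#' @export
setMethod("bags", "BagCohort", function(x) x@bags)

#' @rdname BagCohort-accessors
#' @export
setMethod("survivalData", "BagCohort", function(x) x@survival)

#' @rdname BagCohort-accessors
#' @export
setMethod("featureDim", "BagCohort", function(x) ncol(x@bags[[1]]))

#' @rdname BagCohort-accessors
#' @export
setMethod("nBags", "BagCohort", function(x) length(x@bags))

#' @rdname BagCohort-accessors
#' @export
setMethod("bagSizes", "BagCohort",
          function(x) vapply(x@bags, nrow, integer(1)))

#' @describeIn BagCohort-accessors subset a cohort by index, id or logical.
#' @param i index, character bag_ids, or logical vector.
#' @param j,drop,... ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "BagCohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@bags))
  if (anyNA(i)) stop("unknown bag_id in subset")
  new("BagCohort", bags = x@bags[i],
      survival = {
        s <- x@survival[i, , drop = FALSE]; rownames(s) <- NULL; s
      })
})

## full-precision numeric formatting so text round-trips are bit-exact
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  ## shorten where fewer digits already round-trip (keeps fixtures readable)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

.writeMatrixCSV <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(.fmtNum(r), collapse = ","))
  writeLines(lines, path)
}

.readMatrixCSV <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = ",",
                          colClasses = "numeric", data.table = FALSE)
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a cohort to a manifest plus per-bag matrix files
#'
#' Writes \code{manifest.csv} (columns \code{bag_id,path,time,event}) and one
#' headerless delimited matrix file per bag (one instance per line) under
#' \code{dir/bags/}. Numbers are written with enough digits that
#' [loadCohort()] reproduces the matrices bit-identically.
#'
#' @param cohort a [BagCohort-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @seealso [loadCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "BagCohort"))
  bagdir <- file.path(dir, "bags")
  dir.create(bagdir, recursive = TRUE, showWarnings = FALSE)
  s <- survivalData(cohort)
  rel <- file.path("bags", paste0(s$bag_id, ".csv"))
  for (i in seq_len(nBags(cohort)))
    .writeMatrixCSV(cohort@bags[[i]], file.path(dir, rel[i]))
  man <- data.frame(bag_id = s$bag_id, path = rel,
                    time = .fmtNum(s$time), event = s$event)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load a cohort from a manifest
#'
#' Reads a cohort manifest (CSV with header \code{bag_id,path,time,event};
#' paths resolved relative to the manifest's directory) and the per-bag
#' matrix files it points to.
#'
#' @param manifest_path path to the manifest CSV.
#' @return a [BagCohort-class]; bag order follows the manifest.
#' @examples
#' b <- list(p1 = matrix(1:8 / 3, 4), p2 = matrix(rnorm(6), 3))
#' surv <- data.frame(bag_id = c("p1", "p2"), time = c(5, 7), event = c(1, 0))
#' d <- tempfile(); writeCohort(BagCohort(b, surv), d)
#' loadCohort(file.path(d, "manifest.csv"))
#' @export
loadCohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = c(bag_id = "character"))
  need <- c("bag_id", "path", "time", "event")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(man$bag_id))
    stop("duplicate bag_id in manifest: ",
         paste(unique(man$bag_id[duplicated(man$bag_id)]), collapse = ", "))
  if (!all(man$event %in% c(0, 1)))
    stop("manifest event indicators must be 0 or 1")
  if (any(!is.finite(man$time)) || any(man$time <= 0))
    stop("manifest times must be positive")
  root <- dirname(manifest_path)
  bags <- vector("list", nrow(man))
  names(bags) <- man$bag_id
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(file.path(root, p)) && !file.exists(p))
      stop("bag '", man$bag_id[i], "': matrix file not found: ", p)
    f <- if (file.exists(file.path(root, p))) file.path(root, p) else p
    m <- .readMatrixCSV(f)
    if (any(!is.finite(m)))
      stop("bag '", man$bag_id[i], "' contains non-finite feature values")
    bags[[i]] <- m
  }
  d <- unique(vapply(bags, ncol, integer(1)))
  if (length(d) != 1L)
    stop("feature dimension differs across bags: ",
         paste(d, collapse = ", "))
  BagCohort(bags, man[, c("bag_id", "time", "event")])
}

#' Resample a bag to a fixed number of instances
#'
#' Brings a bag to exactly \code{n_target} rows, mirroring the fixed-size
#' resampling used for whole-slide feature matrices (12,000 tiles on real
#' cohorts): bags with more instances are downsampled by a uniform random
#' subset without replacement; smaller bags keep every original instance and
#' are topped up with uniform draws with replacement.
#'
#' @param bag a single-bag [BagCohort-class] or a numeric matrix.
#' @param n_target desired number of instances (default 12000).
#' @param seed integer seed; the operation is deterministic given the seed.
#' @return object of the same kind as \code{bag}, with \code{n_target} rows
#'   per bag.
#' @export
resampleBag <- function(bag, n_target = 12000L, seed = 1L) {
  if (length(n_target) != 1L || !is.finite(n_target) || n_target < 1)
    stop("n_target must be a positive integer")
  n_target <- as.integer(n_target)
  if (is(bag, "BagCohort")) {
    out <- bag
    for (i in seq_len(nBags(bag)))
      out@bags[[i]] <- resampleBag(bag@bags[[i]], n_target,
                                   seed = seed + i - 1L)
    return(out)
  }
  m <- as.matrix(bag)
  n <- nrow(m)
  if (n == n_target) return(m)
  rng <- .withSeed(seed)
  on.exit(rng())
  idx <- if (n > n_target) {
    sample.int(n, n_target, replace = FALSE)
  } else {
    c(seq_len(n), sample.int(n, n_target - n, replace = TRUE))
  }
  m[idx, , drop = FALSE]
}

## evaluate under a local RNG state; returns a restore function
.withSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
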