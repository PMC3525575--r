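.PAIR_COLS <- c("trait_id", "group", "y1", "y2", "sex1", "sex2",
                "covar1", "covar2")

#' Build a validated twin-pair dataset
#'
#' Bundles a per-pair phenotype table with its \code{\link{trait_spec}} and
#' validates the zygosity-group/sex invariants: same-sex groups must have the
#' matching sex for both members, and \code{DOS} pairs are stored with twin 1
#' male (rows supplied the other way around are swapped). Pairs missing both
#' phenotypes are dropped; pairs missing one phenotype are retained and enter
#' the likelihood through their marginal (single-twin) contribution.
#'
#' @param pairs data.frame with columns \code{trait_id, group, y1, y2, sex1,
#'   sex2, covar1, covar2}. Empty covariates are allowed (\code{NA}).
#' @param spec a \code{\link{trait_spec}}.
#' @return object of class \code{twin_dataset}: list with elements
#'   \code{spec}, \code{pairs} and \code{group_counts}.
#' @export
twin_dataset <- function(pairs, spec) {
  stopifnot(inherits(spec, "trait_spec"), is.data.frame(pairs))
  missing_cols <- setdiff(.PAIR_COLS, names(pairs))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  pairs <- pairs[.PAIR_COLS]
  pairs$trait_id <- as.character(pairs$trait_id)
  pairs$group <- as.character(pairs$group)
  pairs$sex1 <- as.character(pairs$sex1)
  pairs$sex2 <- as.character(pairs$sex2)
  for (cl in c("y1", "y2", "covar1", "covar2"))
    pairs[[cl]] <- as.numeric(pairs[[cl]])

  bad_trait <- which(pairs$trait_id != spec$trait_id)
  if (length(bad_trait))
    stop("trait_id mismatch with spec in row(s): ",
         paste(utils::head(bad_trait, 10L), collapse = ", "), call. = FALSE)

  unknown <- setdiff(unique(pairs$group), .GROUPS)
  if (length(unknown))
    stop("unknown zygosity group label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  # DOS convention: twin 1 male; swap well-formed F/M rows
  flip <- pairs$group == "DOS" & pairs$sex1 == "F" & pairs$sex2 == "M"
  if (any(flip)) {
    pairs[flip, c("y1", "y2")] <- pairs[flip, c("y2", "y1")]
    pairs[flip, c("covar1", "covar2")] <- pairs[flip, c("covar2", "covar1")]
    pairs[flip, c("sex1", "sex2")] <- pairs[flip, c("sex2", "sex1")]
  }

  exp_sex <- do.call(rbind, .GROUP_SEXES[pairs$group])
  bad_sex <- which(pairs$sex1 != exp_sex[, 1] | pairs$sex2 != exp_sex[, 2])
  if (length(bad_sex))
    stop("sex/zygosity-group invariant violated in row(s): ",
         paste(utils::head(bad_sex, 20L), collapse = ", "), call. = FALSE)

  if (spec$scale == "ordinal") {
    y <- c(pairs$y1, pairs$y2)
    bad <- !is.na(y) & (y < 0 | y > spec$n_categories - 1L | y != round(y))
    if (any(bad)) {
      rows <- unique(((which(bad) - 1L) %% nrow(pairs)) + 1L)
      stop("ordinal codes outside {0, ..., K-1} in row(s): ",
           paste(utils::head(sort(rows), 20L), collapse = ", "), call. = FALSE)
    }
  }

  drop <- is.na(pairs$y1) & is.na(pairs$y2)
  if (any(drop)) {
    message(sum(drop), " pair(s) with both phenotypes missing dropped")
    pairs <- pairs[!drop, , drop = FALSE]
  }
  rownames(pairs) <- NULL

  structure(list(spec = spec, pairs = pairs,
                 group_counts = vapply(.GROUPS, function(g)
                   sum(pairs$group == g), integer(1))),
            class = "twin_dataset")
}

#' @export
print.twin_dataset <- function(x, ...) {
  cat("<twin_dataset> trait", x$spec$trait_id, "-", x$spec$scale,
      "scale,", nrow(x$pairs), "pairs\n")
  print(x$group_counts)
  if (isTRUE(attr(x, "covar_standardized")))
    cat("covariates standardized (pooled z-scores)\n")
  invisible(x)
}

#' Read twin pairs from a delimited file
#'
#' Reads a CSV (or TSV, by file extension) with header columns
#' \code{trait_id, group, y1, y2, sex1, sex2, covar1, covar2} and returns a
#' validated \code{\link{twin_dataset}}. Empty cells are treated as missing.
#'
#' @param path file path; \code{.tsv}/\code{.tab} extensions are read as
#'   tab-delimited, anything else as comma-delimited.
#' @param spec a \code{\link{trait_spec}}.
#' @param sep field separator, overriding the extension-based guess.
#' @return a \code{\link{twin_dataset}}.
#' @seealso \code{\link{write_pairs}}
#' @export
read_pairs <- function(path, spec, sep = NULL) {
  sep <- sep %||% if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, na.strings = "",
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  missing_cols <- setdiff(.PAIR_COLS, names(df))
  if (length(missing_cols))
    stop("file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  twin_dataset(df, spec)
}

#' Write twin pairs to a delimited file
#'
#' Inverse of \code{\link{read_pairs}}: numeric fields are written with 17
#' significant digits so a write/read round trip reproduces the dataset
#' exactly. Missing values become empty cells.
#'
#' @param ds a \code{\link{twin_dataset}}.
#' @param path output path; extension selects the separator as in
#'   \code{\link{read_pairs}}.
#' @param force overwrite an existing file.
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(ds, path, force = FALSE) {
  stopifnot(inherits(ds, "twin_dataset"))
  if (file.exists(path) && !force)
    stop("output exists (use force = TRUE to overwrite): ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- ds$pairs
  if (any(grepl(sep, df$trait_id, fixed = TRUE)))
    stop("trait_id contains the field separator", call. = FALSE)
  for (cl in c("y1", "y2", "covar1", "covar2")) {
    v <- df[[cl]]
    df[[cl]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Standardize the age/cohort covariate to pooled z-scores
#'
#' Replaces both covariate columns by z-scores computed from the pooled
#' non-missing covariate values of all individuals (one mean and SD across
#' sexes and zygosity groups, so thresholds and means stay comparable across
#' groups). Missing covariates are set to 0 (the pooled mean); which cells
#' were imputed is recorded in the \code{"covar_imputed"} attribute.
#' Idempotent: an already-standardized dataset is returned unchanged.
#'
#' @param ds a \code{\link{twin_dataset}}.
#' @return the dataset with standardized covariates and attributes
#'   \code{covar_standardized} (flag) and \code{covar_imputed} (logical
#'   two-column matrix).
#' @export
standardize_covariate <- function(ds) {
  stopifnot(inherits(ds, "twin_dataset"))
  if (isTRUE(attr(ds, "covar_standardized"))) return(ds)
  if (ds$spec$covariate_kind == "none") {
    attr(ds, "covar_standardized") <- TRUE
    return(ds)
  }
  v <- c(ds$pairs$covar1, ds$pairs$covar2)
  obs <- v[!is.na(v)]
  if (length(obs) == 0L)
    stop("all covariate values missing but covariate_kind = ",
         ds$spec$covariate_kind, call. = FALSE)
  m <- mean(obs)
  s <- sqrt(mean((obs - m)^2))  # population SD, so z-scores have variance 1
  if (!is.finite(s) || s == 0)
    stop("degenerate covariate: zero variance", call. = FALSE)
  imput <- cbind(covar1 = is.na(ds$pairs$covar1),
                 covar2 = is.na(ds$pairs$covar2))
  z1 <- (ds$pairs$covar1 - m) / s
  z2 <- (ds$pairs$covar2 - m) / s
  z1[imput[, 1]] <- 0
  z2[imput[, 2]] <- 0
  ds$pairs$covar1 <- z1
  ds$pairs$covar2 <- z2
  attr(ds, "covar_standardized") <- TRUE
  attr(ds, "covar_imputed") <- imput
  ds
}
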