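#' Construct a species count inventory
#'
#' An inventory is one site's census: one positive integer count per observed
#' species, optionally tagged with a site label, a taxon group, and a latitude.
#' Zero-count species are by definition unobserved and are never stored.
#'
#' @param counts numeric vector of per-species counts; whole numbers >= 1.
#'   Names, if present, are kept as species labels but carry no meaning beyond
#'   bookkeeping.
#' @param site_id character site label.
#' @param taxon_group optional character label (e.g. "trees", "bats").
#' @param latitude optional latitude in decimal degrees, in \[-90, 90\].
#' @return An object of class `"inventory"`: a list with elements `site_id`,
#'   `taxon_group`, `latitude` and `counts`.
#' @examples
#' inv <- inventory(c(1, 1, 1, 10), site_id = "plot-A")
#' inv
#' @export
inventory <- function(counts, site_id = "site", taxon_group = NULL,
                      latitude = NULL) {
  counts <- check_counts(counts)
  stopifnot(is.character(site_id), length(site_id) == 1L)
  if (!is.null(taxon_group)) {
    stopifnot(is.character(taxon_group), length(taxon_group) == 1L)
  }
  if (!is.null(latitude)) {
    latitude <- check_scalar(latitude, "latitude", lower = -90, upper = 90)
  }
  structure(
    list(site_id = site_id, taxon_group = taxon_group, latitude = latitude,
         counts = counts),
    class = "inventory"
  )
}

#' @export
print.inventory <- function(x, ...) {
  cat(sprintf("Inventory '%s': S = %d species, N = %d individuals\n",
              x$site_id, length(x$counts), sum(x$counts)))
  if (!is.null(x$taxon_group)) cat("  group:   ", x$taxon_group, "\n")
  if (!is.null(x$latitude)) cat("  latitude:", x$latitude, "\n")
  cat("  counts:  ",
      paste(utils::head(sort(x$counts, decreasing = TRUE), 20L),
            collapse = " "),
      if (length(x$counts) > 20L) "..." else "", "\n")
  invisible(x)
}

# Accept either an inventory or a bare numeric vector of counts.
as_counts <- function(x) {
  if (inherits(x, "inventory")) x$counts else check_counts(x)
}

#' Read count inventories from a long-format table
#'
#' Reads a CSV or TSV file with one row per (site, species) pair and columns
#' `site`, `species` and `count` (header required). Optional columns
#' `latitude` and `group` attach metadata to each site; they must be constant
#' within a site. Rows are grouped by site in order of first appearance, and
#' species order within a site is preserved as read.
#'
#' @param path path to the file.
#' @param dialect `"auto"` (by file extension; default), `"csv"` or `"tsv"`.
#' @return A named list of [inventory()] objects, one per distinct site.
#' @seealso [write_inventories()] for the inverse operation.
#' @export
read_inventories <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop("could not parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0L) stop("file contains no data rows: ", path, call. = FALSE)
  needed <- c("site", "species", "count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 1 | abs(cnt - round(cnt)) > 1e-8)
  if (length(bad) > 0L) {
    stop(sprintf("invalid count %s in data row %d (site '%s', species '%s'): counts must be integers >= 1",
                 df$count[bad[1L]], bad[1L], df$site[bad[1L]], df$species[bad[1L]]),
         call. = FALSE)
  }
  sites <- unique(as.character(df$site))
  out <- lapply(sites, function(s) {
    rows <- df[as.character(df$site) == s, , drop = FALSE]
    counts <- round(as.numeric(rows$count))
    names(counts) <- as.character(rows$species)
    lat <- NULL
    if ("latitude" %in% names(rows)) {
      lat_vals <- unique(rows$latitude[!is.na(rows$latitude)])
      if (length(lat_vals) > 1L) {
        stop("site '", s, "' has more than one latitude value", call. = FALSE)
      }
      if (length(lat_vals) == 1L) lat <- as.numeric(lat_vals)
    }
    grp <- NULL
    if ("group" %in% names(rows)) {
      grp_vals <- unique(as.character(rows$group[!is.na(rows$group)]))
      if (length(grp_vals) > 1L) {
        stop("site '", s, "' has more than one group value", call. = FALSE)
      }
      if (length(grp_vals) == 1L) grp <- grp_vals
    }
    inventory(counts, site_id = s, taxon_group = grp, latitude = lat)
  })
  names(out) <- sites
  out
}

#' Write count inventories to a long-format table
#'
#' @param inventories a list of [inventory()] objects (or a single one).
#' @param path output file path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_inventories <- function(inventories, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (inherits(inventories, "inventory")) inventories <- list(inventories)
  rows <- lapply(inventories, function(inv) {
    sp <- names(inv$counts)
    if (is.null(sp)) sp <- paste0("sp", seq_along(inv$counts))
    df <- data.frame(site = inv$site_id, species = sp,
                     count = as.integer(inv$counts),
                     stringsAsFactors = FALSE)
    df$latitude <- if (is.null(inv$latitude)) NA_real_ else inv$latitude
    df$group <- if (is.null(inv$taxon_group)) NA_character_ else inv$taxon_group
    df
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$latitude))) df$latitude <- NULL
  if (all(is.na(df$group))) df$group <- NULL
  utils::write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic inventories from a fitted-model sampler
#'
#' Draws `n_inventories` independent communities of `pool_size` species from
#' the CEGS or PLN sampler and keeps, for each, the species with nonzero
#' counts. This is the package's fixture generator: it produces data whose
#' true model parameters and true pool size are known, so that fitting and
#' diagnostic code can be validated without any external data.
#'
#' @param model `"pln"` or `"cegs"`.
#' @param params a [pln_params()] or [cegs_params()] object matching `model`.
#' @param pool_size true number of species in each community (>= 1).
#' @param n_inventories number of independent communities to draw.
#' @param seed integer seed; the same seed always reproduces the same
#'   inventories and global RNG state is left untouched.
#' @param convention CEGS stopping-probability convention, see [cegs_stop_prob()].
#' @return A named list of [inventory()] objects. Communities in which no
#'   species was observed yield an inventory with zero counts stored; at
#'   realistic parameters this does not occur.
#' @examples
#' fx <- generate_fixture("cegs", cegs_params(2, 1), pool_size = 100,
#'                        n_inventories = 3, seed = 1)
#' sapply(fx, function(inv) length(inv$counts))
#' @export
generate_fixture <- function(model = c("pln", "cegs"), params, pool_size,
                             n_inventories = 1L, seed = NULL,
                             convention = "frechet") {
  model <- match.arg(model)
  pool_size <- check_scalar(pool_size, "pool_size", lower = 1)
  n_inventories <- check_scalar(n_inventories, "n_inventories", lower = 1)
  if (model == "pln" && !inherits(params, "pln_params")) {
    stop("`params` must be a pln_params() object for model 'pln'", call. = FALSE)
  }
  if (model == "cegs" && !inherits(params, "cegs_params")) {
    stop("`params` must be a cegs_params() object for model 'cegs'", call. = FALSE)
  }
  with_seed(seed, {
    out <- vector("list", n_inventories)
    for (i in seq_len(n_inventories)) {
      x <- if (model == "pln") {
        pln_sample(pool_size, params, seed = NULL)
      } else {
        cegs_sample(pool_size, params, seed = NULL, convention = convention)
      }
      x <- x[x > 0]
      id <- sprintf("%s-%03d", model, i)
      inv <- structure(
        list(site_id = id, taxon_group = NULL, latitude = NULL,
             counts = as.numeric(x)),
        class = "inventory"
      )
      out[[i]] <- inv
    }
    names(out) <- vapply(out, function(z) z$site_id, character(1))
    out
  })
}
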