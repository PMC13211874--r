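#' Synthetic synapse table with known partner percentages
#'
#' Builds a connectivity table for one reference cell type whose
#' post-filter partner percentages equal the requested specification
#' exactly, plus planted rows that the filters must remove: connections
#' with fewer than \code{min_synapses} synapses and rows with a missing
#' proofread flag.
#'
#' @param reference_type reference cell type (e.g. "C2")
#' @param partners named numeric vector of target percentages per partner
#'   type (must sum to 100)
#' @param n_reference_cells number of reference cells
#' @param direction \code{"output"} (reference is presynaptic) or
#'   \code{"input"}
#' @param scale synapses per percentage point (counts =
#'   \code{partners * scale}, so every planted connection has >=
#'   \code{3 * scale / min(partners)} synapses; keep
#'   \code{min(partners) * scale >= 3})
#' @param n_low_rows planted sub-threshold rows (2 synapses each)
#' @param n_nan_rows planted rows with missing proofread flag
#' @param seed integer seed (shuffles row order)
#' @return data.frame with columns pre_type, pre_cell_id, post_type,
#'   post_cell_id, n_synapses, proofread, and attribute
#'   \code{planted_percentages}
#' @export
make_synapse_fixture <- function(reference_type = "C2",
                                 partners = c(Mi1 = 40, Tm1 = 35, L5 = 25),
                                 n_reference_cells = 3,
                                 direction = c("output", "input"),
                                 scale = 1, n_low_rows = 2, n_nan_rows = 2,
                                 seed = NULL) {
  direction <- match.arg(direction)
  if (any(partners < 0)) stop("negative partner percentages", call. = FALSE)
  if (abs(sum(partners) - 100) > 1e-9)
    stop("partner percentages must sum to 100", call. = FALSE)
  counts <- round(partners * scale)
  if (any(counts < 3))
    stop("scale too small: planted counts fall below the 3-synapse filter",
         call. = FALSE)
  rows <- list()
  for (r in seq_len(n_reference_cells)) {
    ref_id <- sprintf("%s_%02d", reference_type, r)
    for (p in names(partners)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pre_type = if (direction == "output") reference_type else p,
        pre_cell_id = if (direction == "output") ref_id
                      else sprintf("%s_%02d_%02d", p, r, 1L),
        post_type = if (direction == "output") p else reference_type,
        post_cell_id = if (direction == "output")
          sprintf("%s_%02d_%02d", p, r, 1L) else ref_id,
        n_synapses = counts[[p]], proofread = TRUE)
    }
    # planted filter fodder: sub-threshold and unproofread connections
    if (n_low_rows > 0) for (j in seq_len(n_low_rows)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pre_type = if (direction == "output") reference_type else "WeakPartner",
        pre_cell_id = if (direction == "output") ref_id
                      else sprintf("Weak_%02d_%02d", r, j),
        post_type = if (direction == "output") "WeakPartner" else reference_type,
        post_cell_id = if (direction == "output")
          sprintf("Weak_%02d_%02d", r, j) else ref_id,
        n_synapses = 2L, proofread = TRUE)
    }
    if (n_nan_rows > 0) for (j in seq_len(n_nan_rows)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pre_type = if (direction == "output") reference_type else "UnproofedPartner",
        pre_cell_id = if (direction == "output") ref_id
                      else sprintf("Unp_%02d_%02d", r, j),
        post_type = if (direction == "output") "UnproofedPartner"
                    else reference_type,
        post_cell_id = if (direction == "output")
          sprintf("Unp_%02d_%02d", r, j) else ref_id,
        n_synapses = 10L, proofread = NA)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- with_seed(seed, tab[sample.int(nrow(tab)), , drop = FALSE])
  rownames(tab) <- NULL
  attr(tab, "planted_percentages") <- partners
  tab
}

SYNAPSE_COLUMNS <- c("pre_type", "pre_cell_id", "post_type", "post_cell_id",
                     "n_synapses", "proofread")

#' Filter a synapse table
#'
#' Removes connections that were not proofread (missing flag) first, then
#' connections with fewer than \code{min_synapses} synapses. Row order is
#' preserved.
#'
#' @param table synapse table (columns pre_type, pre_cell_id, post_type,
#'   post_cell_id, n_synapses, proofread)
#' @param min_synapses minimum synapse count to retain a connection
#' @return filtered data.frame with attribute \code{n_removed} =
#'   \code{c(unproofread, low_count)}
#' @export
filter_synapse_table <- function(table, min_synapses = 3) {
  missing_cols <- setdiff(SYNAPSE_COLUMNS, names(table))
  if (length(missing_cols))
    stop("synapse table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(table$n_synapses) | table$n_synapses < 0 |
                 table$n_synapses != round(table$n_synapses))
  if (length(bad))
    stop("malformed n_synapses in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  keep1 <- !is.na(table$proofread)
  out <- table[keep1, , drop = FALSE]
  keep2 <- out$n_synapses >= min_synapses
  res <- out[keep2, , drop = FALSE]
  attr(res, "n_removed") <- c(unproofread = sum(!keep1),
                              low_count = sum(!keep2))
  res
}

#' Partner-type percentages for a reference cell type
#'
#' For each reference cell, the percentage of its synapses (in the given
#' direction) with each partner type; summarized as mean +/- SEM across
#' reference cells. Partner types connected to fewer than
#' \code{min_cell_fraction} of the reference cells are dropped from the
#' display table but kept in each cell's normalization, so the displayed
#' percentages describe each cell's full synaptic budget.
#'
#' @param table a filtered synapse table (see
#'   \code{\link{filter_synapse_table}})
#' @param reference_type reference cell type
#' @param direction \code{"output"} (partners postsynaptic to the
#'   reference) or \code{"input"}
#' @param min_cell_fraction display threshold on the fraction of
#'   reference cells connected to a partner type (inclusive, >=)
#' @return list: \code{display} (data.frame partner_type, direction,
#'   mean_percent, sem_percent, fraction_cells_connected),
#'   \code{all_partners} (same, pre display filter), \code{per_cell}
#'   (cell x partner percentage matrix), \code{n_reference_cells}
#' @export
partner_percentages <- function(table, reference_type,
                                direction = c("output", "input"),
                                min_cell_fraction = 0.7) {
  direction <- match.arg(direction)
  ref_col <- if (direction == "output") "pre_type" else "post_type"
  ref_id_col <- if (direction == "output") "pre_cell_id" else "post_cell_id"
  partner_col <- if (direction == "output") "post_type" else "pre_type"
  sub <- table[table[[ref_col]] == reference_type, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("no %s connections for reference type '%s'",
                 direction, reference_type), call. = FALSE)
  cells <- unique(sub[[ref_id_col]])
  partners <- sort(unique(sub[[partner_col]]))
  per_cell <- matrix(0, nrow = length(cells), ncol = length(partners),
                     dimnames = list(cells, partners))
  dropped_cells <- character(0)
  for (cell in cells) {
    rows <- sub[sub[[ref_id_col]] == cell, , drop = FALSE]
    total <- sum(rows$n_synapses)
    if (total == 0) { dropped_cells <- c(dropped_cells, cell); next }
    agg <- tapply(rows$n_synapses, rows[[partner_col]], sum)
    per_cell[cell, names(agg)] <- 100 * agg / total
  }
  if (length(dropped_cells)) {
    message(length(dropped_cells), " reference cell(s) with zero ",
            direction, " synapses excluded")
    per_cell <- per_cell[!rownames(per_cell) %in% dropped_cells, ,
                         drop = FALSE]
  }
  n_cells <- nrow(per_cell)
  frac_connected <- colMeans(per_cell > 0)
  summarize <- function(keep) {
    data.frame(
      partner_type = partners[keep],
      direction = direction,
      mean_percent = colMeans(per_cell[, keep, drop = FALSE]),
      sem_percent = apply(per_cell[, keep, drop = FALSE], 2, stats::sd) /
        sqrt(n_cells),
      fraction_cells_connected = frac_connected[keep],
      row.names = NULL
    )
  }
  list(display = summarize(frac_connected >= min_cell_fraction),
       all_partners = summarize(rep(TRUE, length(partners))),
       per_cell = per_cell,
       n_reference_cells = n_cells)
}

#' @rdname filter_synapse_table
#' @param path CSV file with header pre_type,pre_cell_id,post_type,
#'   post_cell_id,n_synapses,proofread
#' @export
read_synapse_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SYNAPSE_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("synapse CSV missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$proofread <- as.logical(tab$proofread)
  tab
}
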