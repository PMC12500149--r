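# Reporting: dominant-active-mode tables and per-period equilibria graphs,
# mirroring the structure of the published result tables and pathway
# figures (species by CSP pointer, reactions by TPI/API, with the same
# filtering thresholds).

#' Dominant-active-mode report for one period
#'
#' Evaluates the CSP pointer and the timescale participation index for the
#' period's dominant active mode (mode `M + 1`, fastest-first) at the
#' period's representative time, and applies the reporting filters: species
#' with `Po >= po_min` (default 0.03) and reactions with `|TPI| >= tpi_min`
#' (default 3%), sorted by decreasing magnitude. The mode is classified
#' dissipative when the signed TPI entries sum to a negative value.
#'
#' @param period One row of a [segment_periods()] table (or any list with
#'   `label`, `dominant_mode`, `t_rep`, `start`, `end`).
#' @param traj Trajectory from [integrate_scenario()].
#' @param po_min,tpi_min Reporting thresholds.
#' @param t_rep Optional override of the representative time.
#' @return Object of class `neurocsp_report`: list with `label`, `t_rep`,
#'   `mode`, `tau`, `species` (data.frame name/Po), `reactions` (data.frame
#'   label/TPI), `character` ("dissipative"/"explosive"), the thresholds,
#'   and the pre-filter normalization sums.
#' @export
dominant_mode_report <- function(period, traj, po_min = 0.03,
                                 tpi_min = 0.03, t_rep = NULL) {
  if (is.null(t_rep)) t_rep <- period$t_rep
  if (t_rep < min(traj$times) || t_rep > max(traj$times)) {
    stop("representative time outside the trajectory span")
  }
  y <- state_at(traj, t_rep)
  cs <- csp_decomposition(y, traj$params, t_rep, traj$protocol)
  mode <- period$dominant_mode
  po <- csp_pointer(cs$decomp, mode)
  tpi <- timescale_participation_index(cs$decomp, cs$S, cs$dR, mode)
  sp <- po[po >= po_min]
  sp <- sp[order(-sp)]
  rx <- tpi[abs(tpi) >= tpi_min]
  rx <- rx[order(-abs(rx))]
  structure(list(
    label = period$label, t_rep = t_rep, mode = mode,
    tau = cs$decomp$tau[mode],
    species = data.frame(name = names(sp), Po = as.numeric(sp)),
    reactions = data.frame(label = names(rx), TPI = as.numeric(rx)),
    character = if (sum(tpi) < 0) "dissipative" else "explosive",
    po_min = po_min, tpi_min = tpi_min,
    po_sum = sum(po), tpi_abs_sum = sum(abs(tpi))),
    class = "neurocsp_report")
}

#' @export
print.neurocsp_report <- function(x, ...) {
  cat(sprintf("<%s> mode %d (tau = %.3g s, %s) at t = %g s\n",
              x$label, x$mode, x$tau, x$character, x$t_rep))
  for (i in seq_len(nrow(x$species))) {
    cat(sprintf("  %-12s Po = %.3f\n", x$species$name[i], x$species$Po[i]))
  }
  for (i in seq_len(nrow(x$reactions))) {
    cat(sprintf("  reaction %-4s TPI = %+.1f%%\n",
                x$reactions$label[i], 100 * x$reactions$TPI[i]))
  }
  invisible(x)
}

#' Equilibria graph for one period
#'
#' For every exhausted mode `r <= M` at the period's representative time,
#' computes the amplitude participation index and the CSP pointer. A
#' reaction is classified by its maximal `|API|` over the exhausted modes:
#' strong when `|API| > strong_min` (default 9%), weak when
#' `weak_min <= |API| <= strong_min` (default 2-9%). Species are listed when
#' any exhausted-mode pointer entry exceeds `po_min` (default 45%).
#' Per-item provenance (the contributing mode) is retained.
#'
#' @inheritParams dominant_mode_report
#' @param strong_min,weak_min,po_min Classification thresholds.
#' @return Object of class `neurocsp_graph`: list with `reactions`
#'   (data.frame label/class/API/mode), `species` (data.frame name/Po/mode),
#'   thresholds and period metadata. Empty (with a warning) when `M = 0`.
#' @export
equilibria_graph <- function(period, traj, strong_min = 0.09,
                             weak_min = 0.02, po_min = 0.45, t_rep = NULL) {
  if (is.null(t_rep)) t_rep <- period$t_rep
  M <- period$M
  meta <- list(label = period$label, t_rep = t_rep, M = M,
               strong_min = strong_min, weak_min = weak_min, po_min = po_min)
  if (M < 1) {
    warning("period ", period$label, " has no exhausted modes; empty graph")
    return(structure(c(meta, list(
      reactions = data.frame(label = character(), class = character(),
                             API = numeric(), mode = integer()),
      species = data.frame(name = character(), Po = numeric(),
                           mode = integer()))),
      class = "neurocsp_graph"))
  }
  y <- state_at(traj, t_rep)
  cs <- csp_decomposition(y, traj$params, t_rep, traj$protocol)
  K <- length(cs$R)
  api_best <- stats::setNames(numeric(K), names(cs$R))
  api_mode <- stats::setNames(integer(K), names(cs$R))
  sp_best <- stats::setNames(numeric(29), state_names())
  sp_mode <- stats::setNames(integer(29), state_names())
  for (r in seq_len(M)) {
    api <- amplitude_participation_index(cs$decomp, cs$S, cs$R, r)
    upd <- !is.na(api) & abs(api) > abs(api_best)
    api_best[upd] <- api[upd]; api_mode[upd] <- r
    po <- csp_pointer(cs$decomp, r)
    upd <- po > sp_best
    sp_best[upd] <- po[upd]; sp_mode[upd] <- r
  }
  cls <- ifelse(abs(api_best) > strong_min, "strong",
         ifelse(abs(api_best) >= weak_min, "weak", NA))
  keep <- !is.na(cls)
  reactions <- data.frame(label = names(api_best)[keep], class = cls[keep],
                          API = as.numeric(api_best[keep]),
                          mode = as.integer(api_mode[keep]))
  reactions <- reactions[order(-abs(reactions$API)), ]
  rownames(reactions) <- NULL
  keep <- sp_best > po_min
  species <- data.frame(name = names(sp_best)[keep],
                        Po = as.numeric(sp_best[keep]),
                        mode = as.integer(sp_mode[keep]))
  species <- species[order(-species$Po), ]
  rownames(species) <- NULL
  structure(c(meta, list(reactions = reactions, species = species)),
            class = "neurocsp_graph")
}

#' @export
print.neurocsp_graph <- function(x, ...) {
  cat(sprintf("<%s equilibria> M = %d at t = %g s: %d reactions (%d strong), %d species\n",
              x$label, x$M, x$t_rep, nrow(x$reactions),
              sum(x$reactions$class == "strong"), nrow(x$species)))
  invisible(x)
}

#' Write report artifacts
#'
#' Writes the dominant-mode reports as CSV tables (one per period, mirroring
#' the published table columns), the equilibria graphs as node/edge lists
#' (TSV) plus a JSON rendition, and a JSON run manifest. Output is
#' deterministic for fixed inputs.
#'
#' @param reports List of [dominant_mode_report()] objects (may be empty).
#' @param graphs List of [equilibria_graph()] objects (may be empty).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(reports, graphs, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character()
  wr <- function(x, f) {
    path <- file.path(out_dir, f)
    tryCatch(x(path), error = function(e) {
      stop("failed writing ", path, ": ", conditionMessage(e))
    })
    written <<- c(written, path)
  }
  for (rep in reports) {
    tab <- merge_report_table(rep)
    wr(function(p) utils::write.csv(tab, p, row.names = FALSE),
       paste0("dominant_mode_", rep$label, ".csv"))
  }
  for (gr in graphs) {
    wr(function(p) utils::write.table(
         gr$reactions, p, sep = "\t", row.names = FALSE, quote = FALSE),
       paste0("equilibria_edges_", gr$label, ".tsv"))
    wr(function(p) utils::write.table(
         gr$species, p, sep = "\t", row.names = FALSE, quote = FALSE),
       paste0("equilibria_nodes_", gr$label, ".tsv"))
    wr(function(p) jsonlite::write_json(
         unclass(gr), p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
       paste0("equilibria_", gr$label, ".json"))
  }
  manifest <- list(
    package = "neurocsp",
    version = as.character(utils::packageVersion("neurocsp")),
    n_reports = length(reports), n_graphs = length(graphs),
    periods = vapply(reports, `[[`, "", "label"),
    thresholds = if (length(reports)) {
      list(po_min = reports[[1]]$po_min, tpi_min = reports[[1]]$tpi_min)
    } else NULL)
  wr(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                      digits = NA, pretty = TRUE),
     "manifest.json")
  invisible(written)
}

# long-format table for one report: rows are species then reactions
merge_report_table <- function(rep) {
  rbind(
    if (nrow(rep$species)) {
      data.frame(period = rep$label, t_rep = rep$t_rep, mode = rep$mode,
                 kind = "species", item = rep$species$name,
                 value = rep$species$Po)
    },
    if (nrow(rep$reactions)) {
      data.frame(period = rep$label, t_rep = rep$t_rep, mode = rep$mode,
                 kind = "reaction", item = rep$reactions$label,
                 value = rep$reactions$TPI)
    })
}

#' Read back a dominant-mode report CSV
#'
#' @param path CSV written by [write_outputs()].
#' @return data.frame in the long format of the written table.
#' @export
read_report_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
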