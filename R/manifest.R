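#' Enumerate a rigid-residue scan
#'
#' Builds the job list for a scan: one unperturbed run plus one rigid-residue
#' run per residue, for each state, with per-job frame counts and the total
#' analyzed simulation time.  The molecular dynamics itself is external; the
#' manifest is a machine-readable job sheet an MD engine driver could consume.
#'
#' @param n_residues number of residues to scan (R >= 1).
#' @param states character vector of state labels (e.g.
#'   \code{c("unbound", "bound")}).
#' @param total_ns per-job trajectory length, ns.
#' @param discard_ns initial window discarded as equilibration, ns.
#' @param interval_ps analysis frame interval, ps; must divide the remaining
#'   duration into an integer frame count.
#' @return Object of class \code{"ScanManifest"}: \code{jobs} (data frame:
#'   \code{run_id}, \code{state}, \code{rigid_residue}, \code{total_ns},
#'   \code{discard_ns}, \code{frame_interval_ps}, \code{frames_analyzed}) and
#'   \code{totals} (\code{job_count}, \code{total_analyzed_ns},
#'   \code{frames_per_job}).
#' @examples
#' m <- build_manifest(94, c("unbound", "bound"), 34, 4, 2)
#' m$totals$job_count           # 190
#' m$totals$frames_per_job      # 15000
#' m$totals$total_analyzed_ns   # 5700
#' @export
build_manifest <- function(n_residues, states, total_ns, discard_ns, interval_ps) {
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 1L) stop("'n_residues' must be >= 1")
  if (!length(states)) stop("need at least one state")
  if (total_ns <= discard_ns) stop("'total_ns' must exceed 'discard_ns'")
  frames <- (total_ns - discard_ns) * 1000 / interval_ps
  if (abs(frames - round(frames)) > 1e-9)
    stop("interval (", interval_ps, " ps) does not divide the analyzed window (",
         total_ns - discard_ns, " ns) into an integer frame count")
  frames <- as.integer(round(frames))
  jobs <- expand.grid(rigid_residue = 0:n_residues, state = states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jobs <- jobs[order(match(jobs$state, states), jobs$rigid_residue), ]
  jobs <- data.frame(run_id = sprintf("%s_r%03d", jobs$state, jobs$rigid_residue),
                     state = jobs$state, rigid_residue = jobs$rigid_residue,
                     total_ns = total_ns, discard_ns = discard_ns,
                     frame_interval_ps = interval_ps, frames_analyzed = frames,
                     stringsAsFactors = FALSE)
  rownames(jobs) <- NULL
  structure(list(jobs = jobs,
                 totals = list(job_count = nrow(jobs),
                               frames_per_job = frames,
                               total_analyzed_ns = nrow(jobs) * (total_ns - discard_ns))),
            class = "ScanManifest")
}

#' @export
print.ScanManifest <- function(x, ...) {
  states <- unique(x$jobs$state)
  cat("ScanManifest:", x$totals$job_count, "jobs (",
      length(states), "states x", max(x$jobs$rigid_residue), "residues + unperturbed )\n")
  cat("  frames per job:", x$totals$frames_per_job,
      "( every", x$jobs$frame_interval_ps[1], "ps after",
      x$jobs$discard_ns[1], "ns discard )\n")
  cat("  total analyzed:", x$totals$total_analyzed_ns, "ns\n")
  invisible(x)
}

#' Serialize / restore a scan manifest as CSV
#'
#' Round-trips losslessly: the totals are recomputed from the job table.
#'
#' @param manifest a \code{ScanManifest}.
#' @param file output path.
#' @return \code{file} invisibly (write); a \code{ScanManifest} (read).
#' @export
write_manifest_csv <- function(manifest, file) {
  stopifnot(inherits(manifest, "ScanManifest"))
  utils::write.csv(manifest$jobs, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(file) {
  jobs <- utils::read.csv(file, stringsAsFactors = FALSE)
  structure(list(jobs = jobs,
                 totals = list(job_count = nrow(jobs),
                               frames_per_job = jobs$frames_analyzed[1],
                               total_analyzed_ns = sum(jobs$total_ns - jobs$discard_ns))),
            class = "ScanManifest")
}
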