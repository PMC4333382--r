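#' Fragments per kilobase of transcript per million mapped fragments
#'
#' @param count Mapped fragment count for the transcript.
#' @param transcript_length Transcript length, bp (> 0).
#' @param library_total Total mapped fragments in the library (> 0).
#' @return FPKM = \code{count * 1e9 / (transcript_length * library_total)}.
#'   Vectorised over \code{count} and \code{transcript_length}.
#' @examples
#' fpkm(100, 1000, 1e7)   # 10
#' @export
fpkm <- function(count, transcript_length, library_total) {
  if (any(transcript_length <= 0) || any(library_total <= 0))
    stop("invalid denominator: transcript_length and library_total must be positive",
         call. = FALSE)
  count * 1e9 / (transcript_length * library_total)
}

#' Construct a RIP library
#'
#' @param library_id Library identifier.
#' @param condition Treatment condition, \code{"DMSO"} or \code{"YK4279"}.
#' @param antibody One of \code{"RHA"}, \code{"FLI1"}, \code{"RHA_block"},
#'   \code{"FLI1_block"}, \code{"IgG"}.
#' @param values Named numeric vector of FPKM values (names are transcript
#'   ids, unique; values non-negative).
#' @return Object of class \code{"rip_library"}.
#' @export
rip_library <- function(library_id, condition = c("DMSO", "YK4279"),
                        antibody = c("RHA", "FLI1", "RHA_block",
                                     "FLI1_block", "IgG"),
                        values) {
  condition <- match.arg(condition)
  antibody <- match.arg(antibody)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be named by unique transcript ids", call. = FALSE)
  if (any(values < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  structure(list(library_id = library_id, condition = condition,
                 antibody = antibody, values = values),
            class = "rip_library")
}

#' @export
print.rip_library <- function(x, ...) {
  cat(sprintf("RIP library %s: %s / %s, %d transcripts (%d above 0.5 FPKM)\n",
              x$library_id, x$condition, x$antibody, length(x$values),
              sum(x$values > 0.5)))
  invisible(x)
}

#' Call RIP transcripts at an FPKM threshold
#'
#' Transcripts with FPKM strictly greater than the threshold are called as
#' immunoprecipitated; those at or below it are non-RIP.  The default
#' threshold is 0.5 FPKM, with the boundary value itself treated as
#' non-RIP.
#'
#' @param library A \code{"rip_library"} (or a named FPKM vector).
#' @param threshold FPKM threshold (default 0.5).
#' @return Character vector of called transcript ids.
#' @export
call_rip <- function(library, threshold = 0.5) {
  stopifnot(threshold >= 0)
  values <- if (inherits(library, "rip_library")) library$values else library
  names(values)[values > threshold]
}

#' Subtract a blocked-antibody control library
#'
#' Transcripts called in the immunogenic-peptide-blocked control are
#' removed from the unblocked antibody's call set as nonspecific.
#'
#' @param target,blocked \code{"rip_library"} objects (or named FPKM
#'   vectors) for the unblocked antibody and its blocked control.
#' @param threshold FPKM calling threshold applied to both.
#' @return Character vector: \code{call_rip(target)} minus
#'   \code{call_rip(blocked)}.
#' @export
subtract_blocked <- function(target, blocked, threshold = 0.5) {
  setdiff(call_rip(target, threshold), call_rip(blocked, threshold))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Hypergeometric upper-tail overlap significance
#'
#' Probability of observing at least \code{k} common transcripts between a
#' set of size \code{K} and a set of size \code{n} drawn from a universe of
#' \code{N}: \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n).
#' The tail is summed in log space from log-gamma binomial coefficients, so
#' extreme overlaps (p of order 1e-300 and beyond) are reportable through
#' \code{log10_p} even when \code{p} itself underflows to zero.
#'
#' @param N Universe size.
#' @param K Size of the first set.
#' @param n Size of the second set.
#' @param k Observed overlap, \code{0 <= k <= min(K, n)}.
#' @return List with \code{p} (upper-tail probability; 0 if it underflows)
#'   and \code{log10_p}.
#' @examples
#' hypergeom_overlap(10, 5, 4, 3)   # p = 55/210
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("invalid counts: need 0 <= k <= min(K, n) and K, n <= N",
         call. = FALSE)
  if (k == 0) return(list(p = 1, log10_p = 0))
  x <- k:min(K, n)
  log_terms <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  lp <- .logsumexp(log_terms)
  lp <- min(lp, 0)                       # guard rounding above log(1)
  list(p = exp(lp), log10_p = lp / log(10))
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Four-way partition of control-common transcripts after treatment
#'
#' Classifies every transcript that was common to both immunoprecipitations
#' under control conditions by where it appears after treatment: retained
#' (both treated IPs), EWS-FLI1 only, RHA only, or lost (neither).
#' Percentages are rounded half-away-from-zero to integers.
#'
#' @param control_common Character vector of transcripts common to both
#'   control IPs (non-empty).
#' @param ef_treated,rha_treated Character vectors of transcripts called in
#'   the treated EWS-FLI1 and RHA IPs.
#' @return Object of class \code{"partition_result"}: \code{counts} (named:
#'   retained, ef_only, rha_only, lost), \code{percents} (integers),
#'   \code{total} and the per-class transcript id lists in \code{members}.
#' @export
partition_treatment <- function(control_common, ef_treated, rha_treated) {
  if (length(control_common) == 0L)
    stop("empty input: control_common has no transcripts", call. = FALSE)
  in_ef <- control_common %in% ef_treated
  in_rha <- control_common %in% rha_treated
  members <- list(
    retained = control_common[in_ef & in_rha],
    ef_only = control_common[in_ef & !in_rha],
    rha_only = control_common[!in_ef & in_rha],
    lost = control_common[!in_ef & !in_rha])
  counts <- vapply(members, length, 1L)
  total <- length(control_common)
  structure(
    list(counts = counts,
         percents = as.integer(.round_half_away(100 * counts / total)),
         total = total, members = members),
    class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  lab <- c("retained by both", "EWS-FLI1 only", "RHA only", "lost")
  cat(sprintf("Treatment partition of %d control-common transcripts:\n",
              x$total))
  for (i in seq_along(x$counts))
    cat(sprintf("  %-16s %5d (%d%%)\n", lab[i], x$counts[i], x$percents[i]))
  invisible(x)
}

#' @export
as.data.frame.partition_result <- function(x, ...) {
  data.frame(class = names(x$counts), count = unname(x$counts),
             percent = x$percents)
}

#' Unique and shared shares of the transcript universe
#'
#' Percentage of the universe called only in the RHA IP, only in the
#' EWS-FLI1 IP, in neither, or in both.  The four shares sum to 100 before
#' rounding.
#'
#' @param rha_set,ef_set Character vectors of called transcripts, both
#'   subsets of \code{universe}.
#' @param universe Character vector of all quantified transcripts.
#' @return Named numeric vector (percent): \code{rha_only}, \code{ef_only},
#'   \code{neither}, \code{overlap}.
#' @export
unique_fractions <- function(rha_set, ef_set, universe) {
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  if (!all(rha_set %in% universe) || !all(ef_set %in% universe))
    stop("universe mismatch: sets must be contained in the universe",
         call. = FALSE)
  in_r <- universe %in% rha_set
  in_e <- universe %in% ef_set
  100 * c(rha_only = sum(in_r & !in_e),
          ef_only = sum(in_e & !in_r),
          neither = sum(!in_r & !in_e),
          overlap = sum(in_r & in_e)) / length(universe)
}

#' Run the full RIP-seq downstream pipeline on a set of libraries
#'
#' Calls each library at the FPKM threshold, subtracts the matching
#' blocked-antibody controls, forms the control-common set, tests its
#' overlap against the hypergeometric null, and partitions it by the
#' treated calls.
#'
#' @param libraries Named list of \code{"rip_library"} objects with names
#'   \code{control_rha}, \code{control_fli1}, \code{control_rha_block},
#'   \code{control_fli1_block}, \code{treated_rha}, \code{treated_fli1},
#'   \code{treated_rha_block}, \code{treated_fli1_block} (as produced by
#'   \code{\link{gen_rip_tables}}).
#' @param threshold FPKM calling threshold (default 0.5).
#' @param universe Universe for the overlap test; defaults to all
#'   transcripts present in the control libraries.
#' @return List with the called sets, \code{common}, \code{overlap_test}
#'   (from \code{\link{hypergeom_overlap}}), \code{shares} (from
#'   \code{\link{unique_fractions}}) and \code{partition}.
#' @export
rip_pipeline <- function(libraries, threshold = 0.5, universe = NULL) {
  need <- c("control_rha", "control_fli1", "control_rha_block",
            "control_fli1_block", "treated_rha", "treated_fli1",
            "treated_rha_block", "treated_fli1_block")
  stopifnot(all(need %in% names(libraries)))
  if (is.null(universe))
    universe <- union(names(libraries$control_rha$values),
                      names(libraries$control_fli1$values))
  rha <- subtract_blocked(libraries$control_rha,
                          libraries$control_rha_block, threshold)
  ef <- subtract_blocked(libraries$control_fli1,
                         libraries$control_fli1_block, threshold)
  rha_t <- subtract_blocked(libraries$treated_rha,
                            libraries$treated_rha_block, threshold)
  ef_t <- subtract_blocked(libraries$treated_fli1,
                           libraries$treated_fli1_block, threshold)
  common <- intersect(rha, ef)
  list(
    rha_set = rha, ef_set = ef,
    rha_treated = rha_t, ef_treated = ef_t,
    common = common,
    overlap_test = hypergeom_overlap(length(universe), length(rha),
                                     length(ef), length(common)),
    shares = unique_fractions(rha, ef, universe),
    partition = partition_treatment(common, ef_t, rha_t))
}
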