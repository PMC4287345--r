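# Survival stratification of treated patients by region mutation status,
# with in-package product-limit and log-rank machinery.

#' Classify treated patients by resistance-region mutation status
#'
#' Stratifies patients into three groups for survival comparison: those
#' with a missense mutation inside a region associated with resistance to
#' their drug (`resistant_pfr_mutated`), those mutated elsewhere in the
#' genes owning such regions (`other_region_mutated`), and those with no
#' mutation in those genes (`gene_unmutated`). A patient mutated both
#' inside and outside a resistance region takes the resistance label
#' (presence of the resistance lesion dominates).
#'
#' @param clinical data.frame(`patient_id`, `drug_id`, `time_days`,
#'   `event`).
#' @param mutations Mutation table with `sample_id` = patient id.
#' @param resistance_regions Region table restricted to
#'   resistance-direction associations for the treating drug(s).
#' @param profiled Character vector of patients with mutation data;
#'   patients outside it are excluded (count in attribute `n_excluded`).
#'   Default: all clinical patients (absent from `mutations` = unmutated).
#' @return Named character vector patient_id -> group label, with attribute
#'   `n_excluded`.
#' @export
classify_patients <- function(clinical, mutations, resistance_regions,
                              profiled = NULL) {
  require_columns(clinical, c("patient_id", "drug_id", "time_days", "event"),
                  "clinical")
  require_columns(mutations, c("sample_id", "gene_id", "isoform_id", "position"),
                  "mutations")
  patients <- unique(clinical$patient_id)
  if (is.null(profiled)) profiled <- patients
  excluded <- setdiff(patients, profiled)
  patients <- intersect(patients, profiled)

  asg <- assign_mutations_to_regions(mutations, resistance_regions)
  in_region <- unique(asg$sample_id)
  genes <- unique(resistance_regions$gene_id)
  in_gene <- unique(mutations$sample_id[mutations$gene_id %in% genes])

  label <- rep("gene_unmutated", length(patients))
  label[patients %in% in_gene] <- "other_region_mutated"
  label[patients %in% in_region] <- "resistant_pfr_mutated"
  structure(setNames(label, patients), n_excluded = length(excluded))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1): event observed (`TRUE`) vs censored.
#'   At tied times, events are processed before censorings.
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `n_censor` (censorings at that exact time) and
#'   `surv`, the survival probability just after `time`. `S(0) = 1` is
#'   implicit; the estimate is right-continuous and non-increasing.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))$surv  # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L || length(times) != length(events)) {
    stop_input("`times` and `events` must be non-empty and of equal length")
  }
  if (any(times < 0)) stop_input("survival times must be non-negative")
  events <- as.logical(events)
  tt <- sort(unique(times[events]))
  n_risk <- n_event <- n_censor <- integer(length(tt))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    t <- tt[i]
    n_risk[i] <- sum(times >= t)   # censored at t are still at risk at t
    n_event[i] <- sum(times == t & events)
    n_censor[i] <- sum(times == t & !events)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  data.frame(time = tt, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' K-sample log-rank test
#'
#' Standard unweighted log-rank comparison of two or more survival curves:
#' at each distinct event time the observed events per group are compared
#' with their expectation under the pooled hazard; the quadratic form of
#' the observed-minus-expected vector in its hypergeometric covariance
#' yields a chi-square statistic on k-1 degrees of freedom.
#'
#' @param groups List of two or more non-empty lists/data.frames, each with
#'   elements `times` and `events`.
#' @return List: `statistic`, `df`, `p`, `observed`, `expected` (per
#'   group), and for k = 2 `direction`, the index of the group with more
#'   observed than expected events (worse survival).
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2L) stop_input("log-rank test needs at least 2 groups")
  k <- length(groups)
  times <- lapply(groups, function(g) g$times %||% g$time)
  events <- lapply(groups, function(g) as.logical(g$events %||% g$event))
  if (any(vapply(times, length, 1L) == 0L)) {
    stop_input("log-rank test: every group must be non-empty")
  }
  all_t <- unlist(times)
  all_e <- unlist(events)
  grp <- rep(seq_len(k), vapply(times, length, 1L))
  tt <- sort(unique(all_t[all_e]))

  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in tt) {
    at_risk <- all_t >= t
    n <- sum(at_risk)
    d <- sum(all_t == t & all_e)
    if (n == 0L || d == 0L) next
    ng <- vapply(seq_len(k), function(g) sum(at_risk & grp == g), numeric(1))
    dg <- vapply(seq_len(k), function(g) sum(all_t == t & all_e & grp == g),
                 numeric(1))
    O <- O + dg
    E <- E + ng * d / n
    if (n > 1L) {
      c0 <- d * (n - d) / (n - 1)
      for (g in seq_len(k)) for (h in seq_len(k)) {
        V[g, h] <- V[g, h] + if (g == h) {
          c0 * ng[g] / n * (1 - ng[g] / n)
        } else {
          -c0 * ng[g] * ng[h] / n^2
        }
      }
    }
  }
  oe <- (O - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  stat <- if (all(abs(oe) < .Machine$double.eps^0.5) || all(Vs == 0)) 0 else {
    drop(t(oe) %*% solve(Vs, oe))
  }
  out <- list(statistic = stat, df = k - 1L,
              p = pchisq(stat, df = k - 1L, lower.tail = FALSE),
              observed = O, expected = E)
  if (k == 2L) out$direction <- which.max(O - E)
  out
}

#' Three-group survival comparison of a treated cohort
#'
#' Convenience wrapper tying [classify_patients()] to [logrank_test()]:
#' emits the k-sample statistic over all represented groups plus every
#' pairwise contrast.
#'
#' @inheritParams classify_patients
#' @return List with `labels`, `fits` (per-group [kaplan_meier()] tables),
#'   `logrank` (overall test) and `pairwise` (named list of two-group
#'   tests).
#' @export
survival_stratification <- function(clinical, mutations, resistance_regions,
                                    profiled = NULL) {
  labels <- classify_patients(clinical, mutations, resistance_regions,
                              profiled = profiled)
  cl <- clinical[clinical$patient_id %in% names(labels), , drop = FALSE]
  cl$group <- unname(labels[cl$patient_id])
  present <- unique(cl$group)
  groups <- lapply(present, function(g) {
    list(times = cl$time_days[cl$group == g],
         events = as.logical(cl$event[cl$group == g]))
  })
  names(groups) <- present
  fits <- lapply(groups, function(g) kaplan_meier(g$times, g$events))
  overall <- if (length(groups) >= 2L) logrank_test(groups) else NULL
  pairwise <- list()
  if (length(groups) >= 2L) {
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      pairwise[[paste(names(groups)[i], names(groups)[j], sep = " vs ")]] <-
        logrank_test(groups[c(i, j)])
    }
  }
  list(labels = labels, fits = fits, logrank = overall, pairwise = pairwise)
}
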