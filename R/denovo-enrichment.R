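# De novo enrichment module: the matched gene-permutation null (exon length
# +/- 100 bp, GC +/- 2.5%), length/GC-adjusted odds ratio, permutation p,
# and inverse-variance fixed-effects meta-analysis with Cochran's Q.

.denovoTypeTokens <- c("missense", "nonsense", "frameshift", "stoploss",
                       "del_aa", "inframe", "splice", "synonymous")
# precedence for multi-annotated events: any coding type beats synonymous
.denovoTypePrecedence <- c("nonsense", "frameshift", "splice", "stoploss",
                           "missense", "del_aa", "inframe", "synonymous")

#' Filter raw de novo events
#'
#' Events in genes outside the universe are dropped. An event annotated with
#' several mutation-type tokens (comma-separated in `mutation_type`) keeps
#' its single most damaging type with precedence coding > synonymous.
#' Synonymous events are dropped unless `include_synonymous` is `TRUE`.
#' Unknown mutation-type tokens raise an error naming the token.
#'
#' @param events data.frame `study`, `arm` (`case`/`control`), `gene_id`,
#'   `mutation_type`.
#' @param universe a [GeneCatalog-class].
#' @param include_synonymous keep synonymous events?
#' @return the filtered event data.frame.
#' @export
filterEvents <- function(events, universe, include_synonymous = FALSE) {
  stopifnot(all(c("study", "arm", "gene_id", "mutation_type") %in%
                  names(events)),
            is(universe, "GeneCatalog"))
  toks <- strsplit(events$mutation_type, ",", fixed = TRUE)
  toks <- lapply(toks, trimws)
  unknown <- setdiff(unique(unlist(toks)), .denovoTypeTokens)
  if (length(unknown)) {
    stop("unknown mutation-type token(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # most damaging annotation wins (coding > synonymous)
  events$mutation_type <- vapply(toks, function(tt) {
    .denovoTypePrecedence[min(match(tt, .denovoTypePrecedence))]
  }, "")
  inside <- events$gene_id %in% geneIds(universe)
  if (any(!inside)) {
    essLog("filterEvents: dropped %d events in genes outside the universe",
           sum(!inside))
  }
  events <- events[inside, , drop = FALSE]
  if (!include_synonymous) {
    events <- events[events$mutation_type != "synonymous", , drop = FALSE]
  }
  rownames(events) <- NULL
  events
}

#' Matched gene pool for one target gene
#'
#' All universe genes with total exon length within `len_tol_bp` and GC
#' percent within `gc_tol_pct` of the target; always includes the target
#' itself (permutation sampling is with replacement, so a gene whose only
#' match is itself self-swaps).
#'
#' @param target_gene gene id of the target.
#' @param universe a [GeneCatalog-class].
#' @param len_tol_bp exon-length tolerance in bp (default 100).
#' @param gc_tol_pct GC tolerance in percentage points (default 2.5).
#' @return character vector of matched gene ids.
#' @export
buildMatchPool <- function(target_gene, universe, len_tol_bp = 100,
                           gc_tol_pct = 2.5) {
  pools <- matchPools(universe, target_gene, len_tol_bp, gc_tol_pct)
  geneIds(universe)[pools[[1]]]
}

# Index-based pools for a set of target genes (list of integer vectors into
# the universe), used by the permutation engine.
matchPools <- function(universe, target_genes, len_tol_bp = 100,
                       gc_tol_pct = 2.5) {
  g <- geneTable(universe)
  ti <- match(target_genes, g$gene_id)
  if (anyNA(ti)) {
    stop("target gene(s) not in universe: ",
         paste(target_genes[is.na(ti)], collapse = ", "), call. = FALSE)
  }
  lapply(ti, function(i) {
    which(abs(g$exon_length_bp - g$exon_length_bp[i]) <= len_tol_bp &
            abs(g$gc_pct - g$gc_pct[i]) <= gc_tol_pct)
  })
}

# Add-one permutation p for enrichment given replicate in-set counts.
permPValueFromCounts <- function(counts, obs) {
  (1 + sum(counts >= obs)) / (1 + length(counts))
}

#' Matched permutation test for one study/arm
#'
#' `obs_in_set` is the number of events whose gene lies in `gene_set`. Each
#' permutation replicate independently exchanges each event's gene for
#' another gene drawn uniformly (with replacement across events) from that
#' gene's matched pool, excluding the gene itself. Excluding the target
#' keeps the permutation expectation unbiased under enrichment (the pool
#' minus the event gene has the background set composition). Events whose
#' gene has no other matched gene cannot be exchanged and are, by default,
#' excluded from the analysis with a logged count (`unmatched = "self"`
#' keeps them as identity self-swaps instead, which is conservative: their
#' expectation contribution equals their observation). `exp_in_set` is the
#' replicate mean of in-set counts. The
#' length/GC-adjusted odds ratio is
#' `[obs / (n - obs)] / [exp / (n - exp)]` with `n` the number of events.
#' The permutation p is add-one, `(1 + #\{count >= obs\}) / (1 + n_perm)`,
#' one-sided for enrichment; the two-sided value doubles it (capped at 1).
#' The meta-analysis SE is the standard deviation of the replicate log-odds
#' (0.5 continuity correction on replicate counts of 0 or n). The exact
#' expectation `sum over events of |pool ∩ set| / |pool|` is always
#' computed and stored alongside the Monte-Carlo mean.
#'
#' @param events data.frame of one study/arm's events (`gene_id` column).
#' @param universe a [GeneCatalog-class].
#' @param gene_set gene-set name (`"EG"`, `"NLG"`) or character vector of
#'   gene ids; must be non-empty.
#' @param n_perm number of permutation replicates (>= 1).
#' @param seed integer RNG seed.
#' @param len_tol_bp,gc_tol_pct matching tolerances.
#' @param per_gene if `TRUE`, one draw per unique gene per replicate is
#'   carried by all of that gene's events (the coarser reading of the
#'   within-study exchange); default resamples per event.
#' @param unmatched policy for events whose gene has no other match:
#'   `"drop"` (default) or `"self"` (identity self-swap).
#' @param check_pools assert, on every replicate, that each resampled gene
#'   satisfies both tolerances w.r.t. the original gene (test mode).
#' @return A [DenovoStudyResult-class].
#' @export
permuteStudy <- function(events, universe, gene_set = "EG", n_perm = 1000L,
                         seed = 1L, len_tol_bp = 100, gc_tol_pct = 2.5,
                         per_gene = FALSE, check_pools = FALSE,
                         unmatched = c("drop", "self")) {
  unmatched <- match.arg(unmatched)
  stopifnot(is(universe, "GeneCatalog"), n_perm >= 1, nrow(events) >= 1)
  set_ids <- if (length(gene_set) == 1L &&
                 gene_set %in% c("EG", "NLG", "OTHER")) {
    geneSet(universe, gene_set)
  } else gene_set
  if (!length(set_ids)) stop("gene_set is empty", call. = FALSE)
  g <- geneTable(universe)
  in_set <- g$gene_id %in% set_ids

  uniq <- unique(events$gene_id)
  pools <- matchPools(universe, uniq, len_tol_bp, gc_tol_pct)
  # the exchange draws "another" gene: drop the target from its own pool
  uniq_idx <- match(uniq, g$gene_id)
  pools <- lapply(seq_along(pools), function(u) {
    setdiff(pools[[u]], uniq_idx[u])
  })
  matchable <- lengths(pools) > 0L
  if (unmatched == "drop") {
    keep <- matchable[match(events$gene_id, uniq)]
    if (any(!keep)) {
      essLog("permuteStudy: dropped %d events on genes with no exchange partner",
             sum(!keep))
      events <- events[keep, , drop = FALSE]
      if (!nrow(events)) {
        stop("no events remain after dropping unmatchable genes",
             call. = FALSE)
      }
      uniq <- unique(events$gene_id)
      pools <- pools[match(uniq, g$gene_id[uniq_idx])]
      uniq_idx <- match(uniq, g$gene_id)
    }
  } else {
    pools[!matchable] <- as.list(uniq_idx[!matchable])
  }
  n <- nrow(events)
  obs <- sum(events$gene_id %in% set_ids)
  ev2uniq <- match(events$gene_id, uniq)
  pool_of_event <- pools[ev2uniq]

  exp_exact <- sum(vapply(pool_of_event, function(p) mean(in_set[p]),
                          numeric(1)))

  counts <- withSeed(seed, {
    cnt <- integer(n_perm)
    if (per_gene) {
      n_by_gene <- tabulate(ev2uniq, nbins = length(uniq))
      for (u in seq_along(uniq)) {
        draws <- pools[[u]][sample.int(length(pools[[u]]), n_perm,
                                       replace = TRUE)]
        if (check_pools) stopifnot(all(
          abs(g$exon_length_bp[draws] -
                g$exon_length_bp[match(uniq[u], g$gene_id)]) <= len_tol_bp,
          abs(g$gc_pct[draws] -
                g$gc_pct[match(uniq[u], g$gene_id)]) <= gc_tol_pct))
        cnt <- cnt + n_by_gene[u] * as.integer(in_set[draws])
      }
    } else {
      for (e in seq_len(n)) {
        p <- pool_of_event[[e]]
        draws <- p[sample.int(length(p), n_perm, replace = TRUE)]
        if (check_pools) {
          oi <- match(events$gene_id[e], g$gene_id)
          stopifnot(all(abs(g$exon_length_bp[draws] -
                              g$exon_length_bp[oi]) <= len_tol_bp),
                    all(abs(g$gc_pct[draws] - g$gc_pct[oi]) <= gc_tol_pct))
        }
        cnt <- cnt + as.integer(in_set[draws])
      }
    }
    cnt
  })
  exp_in_set <- mean(counts)
  if (obs == n && exp_in_set >= n) {
    stop("degenerate study: all events and all expectation in the gene set",
         call. = FALSE)
  }
  adjOdds <- function(k) {
    k <- ifelse(k <= 0, 0.5, ifelse(k >= n, n - 0.5, k))
    k / (n - k)
  }
  log_adj_or <- log(adjOdds(obs)) - log(adjOdds(exp_in_set))
  se <- sd(log(adjOdds(counts)))
  p_one <- permPValueFromCounts(counts, obs)
  new("DenovoStudyResult",
      studyId = as.character(events$study[1] %||% "study"),
      arm = as.character(events$arm[1] %||% "case"),
      nEvents = as.integer(n), obsInSet = as.integer(obs),
      expInSet = exp_in_set, expExact = exp_exact,
      logAdjOR = log_adj_or, seLogOR = se,
      permPOne = p_one, permPTwo = min(1, 2 * p_one),
      nPerm = as.integer(n_perm))
}

#' Inverse-variance fixed-effects meta-analysis with Cochran's Q
#'
#' Weights `w_i = 1 / se_i^2`; combined log-OR `sum(w θ) / sum(w)`; SE
#' `1 / sqrt(sum(w))`; 95% CI `exp(combined +/- 1.96 SE)`; two-sided p from
#' the normal deviate; `Q = sum(w (θ - combined)^2)` on `k - 1` degrees of
#' freedom with an upper-tail chi-square p. A single study returns itself
#' with `Q = 0`, `q_p = 1` (df-0 policy).
#'
#' @param results list of [DenovoStudyResult-class] objects, or a data.frame
#'   with columns `log_adj_or` and `se_log_or` (and optionally `study_id`).
#' @return A [DenovoMetaResult-class].
#' @examples
#' m <- metaFixedEffects(data.frame(log_adj_or = c(0.2, 0.4),
#'                                  se_log_or = c(0.1, 0.2)))
#' round(log(combinedOR(m)), 4)  # 0.24
#' @export
metaFixedEffects <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, is, TRUE, "DenovoStudyResult"))) {
    studies <- data.frame(
      study_id = vapply(results, function(r) r@studyId, ""),
      arm = vapply(results, function(r) r@arm, ""),
      n_events = vapply(results, function(r) r@nEvents, 0L),
      obs_in_set = vapply(results, function(r) r@obsInSet, 0L),
      exp_in_set = vapply(results, function(r) r@expInSet, 0),
      log_adj_or = vapply(results, function(r) r@logAdjOR, 0),
      se_log_or = vapply(results, function(r) r@seLogOR, 0),
      perm_p = vapply(results, function(r) r@permPOne, 0),
      n_perm = vapply(results, function(r) r@nPerm, 0L),
      stringsAsFactors = FALSE)
  } else {
    studies <- as.data.frame(results)
    stopifnot(all(c("log_adj_or", "se_log_or") %in% names(studies)))
    if (is.null(studies$study_id)) {
      studies$study_id <- sprintf("study%d", seq_len(nrow(studies)))
    }
  }
  if (!nrow(studies)) stop("no studies to combine", call. = FALSE)
  if (any(!is.finite(studies$se_log_or) | studies$se_log_or <= 0)) {
    stop("every study needs a finite positive se_log_or", call. = FALSE)
  }
  w <- 1 / studies$se_log_or^2
  theta <- sum(w * studies$log_adj_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (studies$log_adj_or - theta)^2)
  df <- nrow(studies) - 1L
  q_p <- if (df == 0L) 1 else pchisq(q, df, lower.tail = FALSE)
  new("DenovoMetaResult",
      combinedOR = exp(theta),
      ci95 = exp(theta + c(-1.96, 1.96) * se),
      metaP = 2 * pnorm(-abs(theta / se)),
      cochranQ = q, qDf = df, qP = q_p, studies = studies)
}

#' Full de novo enrichment analysis: filter, permute per study, meta-combine
#'
#' Runs [filterEvents()], then [permuteStudy()] per study within each arm
#' (case and control are analyzed separately), and combines each arm's
#' studies by [metaFixedEffects()]. Per-study seeds are derived
#' deterministically from the master seed.
#'
#' @param events data.frame of raw events across studies (`study`, `arm`,
#'   `gene_id`, `mutation_type`).
#' @param universe a [GeneCatalog-class].
#' @param gene_set gene-set name or id vector (see [permuteStudy()]).
#' @param include_synonymous keep synonymous events?
#' @param n_perm permutation replicates per study.
#' @param seed master seed.
#' @param ... further arguments to [permuteStudy()].
#' @return list with elements `case` and `control`, each a list of
#'   `studies` ([DenovoStudyResult-class] list) and `meta`
#'   ([DenovoMetaResult-class]); arms without events are `NULL`.
#' @export
runDenovoAnalysis <- function(events, universe, gene_set = "EG",
                              include_synonymous = FALSE, n_perm = 1000L,
                              seed = 1L, ...) {
  events <- filterEvents(events, universe,
                         include_synonymous = include_synonymous)
  arms <- c("case", "control")
  study_ids <- unique(events$study)
  seeds <- deriveSeeds(seed, length(study_ids) * length(arms))
  dim(seeds) <- c(length(study_ids), length(arms))
  out <- lapply(seq_along(arms), function(ai) {
    arm <- arms[ai]
    res <- list()
    for (si in seq_along(study_ids)) {
      ev <- events[events$study == study_ids[si] & events$arm == arm, ,
                   drop = FALSE]
      if (!nrow(ev)) next
      res[[length(res) + 1L]] <- permuteStudy(ev, universe, gene_set,
                                              n_perm = n_perm,
                                              seed = seeds[si, ai], ...)
    }
    if (!length(res)) return(NULL)
    list(studies = res, meta = metaFixedEffects(res))
  })
  names(out) <- arms
  out
}

#' Read / write de novo event tables
#'
#' TSV columns: `study`, `arm`, `gene_id`, `mutation_type`.
#' @param path file path.
#' @param events event data.frame (for writing).
#' @export
readDenovoEvents <- function(path) {
  readTsv(path)
}

#' @rdname readDenovoEvents
#' @export
writeDenovoEvents <- function(events, path) {
  writeTsv(events, path)
}
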