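#' @include AllClasses.R
NULL

#' Composition stability of transporter traits per taxon
#'
#' For each taxon, restricts to the samples where its total transporter
#' abundance strictly exceeds \code{floor} (avoiding 0/0 compositions),
#' computes the per-sample substrate composition, and summarises it as the
#' mean composition (summing to 1), the per-category standard deviation
#' over samples, and a stability score defined as the maximum s.d. across
#' categories (0 = perfectly stable). Taxa observed in fewer than two
#' samples are omitted with a warning.
#'
#' @param tensor taxon x category x sample array from [aggregateByTaxon()].
#' @param floor minimum taxon total per sample, default 0.
#' @return List with \code{mean} (taxon x category), \code{sd}
#'   (taxon x category), \code{stability} (named numeric) and \code{nSamples}
#'   (samples used per taxon).
#' @export
compositionStability <- function(tensor, floor = 0) {
    if (dim(tensor)[3L] < 2L) stop("need at least two samples")
    taxa <- dimnames(tensor)[[1L]]
    cats <- dimnames(tensor)[[2L]]
    keepTaxa <- character()
    meanM <- sdM <- NULL
    nUsed <- integer()
    for (t in taxa) {
        slab <- tensor[t, , , drop = TRUE]          # category x sample
        if (is.null(dim(slab))) slab <- matrix(slab, ncol = 1L)
        tot <- colSums(slab)
        use <- tot > floor
        if (sum(use) < 2L) {
            warning("taxon '", t, "' present in fewer than two samples; omitted")
            next
        }
        comp <- sweep(slab[, use, drop = FALSE], 2L, tot[use], `/`)
        keepTaxa <- c(keepTaxa, t)
        meanM <- rbind(meanM, rowMeans(comp))
        sdM <- rbind(sdM, apply(comp, 1L, stats::sd))
        nUsed <- c(nUsed, sum(use))
    }
    if (length(keepTaxa) == 0L) stop("no taxon with two or more samples")
    dimnames(meanM) <- dimnames(sdM) <- list(keepTaxa, cats)
    list(mean = meanM, sd = sdM,
         stability = setNames(apply(sdM, 1L, max), keepTaxa),
         nSamples = setNames(nUsed, keepTaxa))
}

#' Gene-abundance versus expression correlation per taxon and category
#'
#' Pairs the MG (gene abundance) and MT (expression) relative abundances
#' of each (taxon, substrate category) across the sampling dates present
#' in both panels and computes a correlation coefficient (Pearson by
#' default, Spearman optional). Relative abundance is each cell's share of
#' the sample's total transporter abundance within its own dataset. Pairs
#' with zero variance on either side are reported as missing.
#'
#' @param mgTensor,mtTensor arrays from [aggregateByTaxon()] for the MG
#'   and MT datasets.
#' @param mgDates,mtDates numeric/character dates parallel to the sample
#'   axes; matching is by exact equality.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param flagThreshold coefficient cutoff for \code{passes_filter}
#'   (strict), default 0.6.
#' @return data.frame with columns taxon, category, n, coefficient,
#'   passes_filter.
#' @export
mgMtCorrelation <- function(mgTensor, mtTensor, mgDates, mtDates,
                            method = c("pearson", "spearman"),
                            flagThreshold = 0.6) {
    method <- match.arg(method)
    matched <- intersect(mgDates, mtDates)
    if (length(matched) < 2L)
        stop("need at least two matched MG/MT dates")
    iMg <- match(matched, mgDates)
    iMt <- match(matched, mtDates)

    relOf <- function(tensor, idx) {
        slab <- tensor[, , idx, drop = FALSE]
        tot <- apply(slab, 3L, sum)
        sweep(slab, 3L, ifelse(tot > 0, tot, 1), `/`)
    }
    relMg <- relOf(mgTensor, iMg)
    relMt <- relOf(mtTensor, iMt)

    taxa <- intersect(dimnames(mgTensor)[[1L]], dimnames(mtTensor)[[1L]])
    cats <- intersect(dimnames(mgTensor)[[2L]], dimnames(mtTensor)[[2L]])
    out <- expand.grid(taxon = taxa, category = cats,
                       stringsAsFactors = FALSE)
    out$n <- length(matched)
    out$coefficient <- NA_real_
    for (i in seq_len(nrow(out))) {
        x <- relMg[out$taxon[i], out$category[i], ]
        y <- relMt[out$taxon[i], out$category[i], ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        out$coefficient[i] <- if (method == "pearson") {
            stats::cor(x, y)
        } else {
            stats::cor(rank(x), rank(y))
        }
    }
    out$passes_filter <- !is.na(out$coefficient) &
        out$coefficient > flagThreshold
    out
}

## --- Spearman rank statistics ------------------------------------------

## Permutation matrices are cached per n; n <= 8 keeps this below 8! rows.
.permEnv <- new.env(parent = emptyenv())

.permutations <- function(n) {
    key <- as.character(n)
    if (!is.null(.permEnv[[key]])) return(.permEnv[[key]])
    perm <- function(v) {
        if (length(v) <= 1L) return(matrix(v, nrow = 1L))
        do.call(rbind, lapply(seq_along(v), function(i) {
            cbind(v[i], perm(v[-i]), deparse.level = 0L)
        }))
    }
    p <- perm(seq_len(n))
    .permEnv[[key]] <- p
    p
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes Spearman's rho on average-ranked data (ties receive mean
#' ranks), which equals the Pearson correlation of the ranks. The two-sided
#' p-value is obtained by exhaustive enumeration of all n! rank
#' permutations when \code{n <= 8} (valid in the presence of ties), and
#' from the t approximation with n - 2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3, no NAs.
#' @return List with \code{rho}, \code{p} and \code{n}; \code{rho} is NA
#'   when either vector is constant.
#' @export
spearmanTest <- function(x, y) {
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (n < 3L) stop("need at least three paired observations")
    rx <- rank(x)
    ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n))
    rho <- stats::cor(rx, ry)
    if (n <= 8L) {
        P <- .permutations(n)
        RY <- matrix(ry[P], nrow(P), n)
        num <- as.vector(RY %*% rx) - n * mean(rx) * mean(ry)
        den <- (n - 1) * stats::sd(rx) * stats::sd(ry)
        rhoPerm <- num / den
        p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    } else {
        t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    list(rho = rho, p = p, n = n)
}

#' Spearman screen of transporters against environmental variables
#'
#' Correlates each transporter's relative abundance series with each
#' environmental variable using [spearmanTest()], dropping missing
#' environment values pairwise. A (transporter, variable) pair passes when
#' the coefficient exceeds \code{rhoThreshold} (on \code{abs(rho)} by
#' default, so strong negative correlations are kept; set
#' \code{useAbsolute = FALSE} for a signed screen) and \code{p < alpha}.
#' A transporter is retained when at least one variable passes. No
#' multiple-testing correction is applied by default;
#' \code{adjust = "BH"} switches the alpha cut to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param relAbund matrix, transporter x sample (e.g.
#'   [relativeAbundance()] of a [ClusterAbundance-class]).
#' @param env data.frame of environmental variables; rows are matched to
#'   the columns of \code{relAbund} by rownames when present, otherwise
#'   positionally.
#' @param rhoThreshold coefficient cutoff (strict), default 0.5.
#' @param alpha p-value cutoff (strict), default 0.05.
#' @param useAbsolute screen on |rho| (default TRUE).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return List with \code{results} (long data.frame: cluster, variable,
#'   n, rho, p, passes) and \code{retained} (character).
#' @export
spearmanEnvScreen <- function(relAbund, env, rhoThreshold = 0.5,
                              alpha = 0.05, useAbsolute = TRUE,
                              adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    env <- as.data.frame(env)
    if (!is.null(rownames(env)) && !is.null(colnames(relAbund)) &&
        all(colnames(relAbund) %in% rownames(env))) {
        env <- env[colnames(relAbund), , drop = FALSE]
    } else if (nrow(env) != ncol(relAbund)) {
        stop("environment table does not match the sample columns")
    }
    numeric <- vapply(env, is.numeric, logical(1))
    env <- env[, numeric, drop = FALSE]

    grid <- expand.grid(cluster = rownames(relAbund),
                        variable = colnames(env),
                        stringsAsFactors = FALSE)
    grid$n <- NA_integer_
    grid$rho <- NA_real_
    grid$p <- NA_real_
    for (i in seq_len(nrow(grid))) {
        x <- relAbund[grid$cluster[i], ]
        y <- env[[grid$variable[i]]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3L) next
        st <- spearmanTest(x[ok], y[ok])
        grid$n[i] <- st$n
        grid$rho[i] <- st$rho
        grid$p[i] <- st$p
    }
    pUse <- if (adjust == "BH") stats::p.adjust(grid$p, "BH") else grid$p
    stat <- if (useAbsolute) abs(grid$rho) else grid$rho
    grid$passes <- !is.na(grid$rho) & !is.na(pUse) &
        stat > rhoThreshold & pUse < alpha
    list(results = grid,
         retained = sort(unique(grid$cluster[grid$passes])))
}

#' Seasonal succession summary of taxon transporter abundance
#'
#' For each taxon, the peak is the sample (ordered by date) with the
#' maximal total transporter abundance; ties take the earlier date. The
#' returned table is ordered by peak date (ties by taxon name), giving the
#' successional sequence of the taxa.
#'
#' @param tensor taxon x category x sample array.
#' @param dates numeric dates parallel to the sample axis.
#' @return data.frame with columns taxon, peak_date, peak_value, ordered
#'   by peak date.
#' @export
successionSummary <- function(tensor, dates) {
    if (dim(tensor)[3L] < 3L) stop("need at least three samples")
    if (length(dates) != dim(tensor)[3L])
        stop("dates must be parallel to the sample axis")
    ord <- order(dates)
    totals <- apply(tensor, c(1L, 3L), sum)[, ord, drop = FALSE]
    dSorted <- dates[ord]
    taxa <- dimnames(tensor)[[1L]]
    peakIdx <- apply(totals, 1L, which.max)      # first max = earliest date
    out <- data.frame(taxon = taxa,
                      peak_date = dSorted[peakIdx],
                      peak_value = totals[cbind(seq_along(taxa), peakIdx)],
                      stringsAsFactors = FALSE)
    out[order(out$peak_date, out$taxon), , drop = FALSE]
}
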