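#' @include AllClasses.R
NULL

## clinical table columns: sample, os_time (> 0), os_event (0/1)
checkClinical <- function(clinical) {
    need <- c("sample", "os_time", "os_event")
    if (!all(need %in% colnames(clinical)))
        stop("clinical table must have columns: ",
             paste(need, collapse = ", "))
    if (any(clinical$os_time <= 0)) stop("os_time must be positive")
    if (anyDuplicated(clinical$sample)) stop("duplicate sample in clinical")
    clinical
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit survival estimates per group and the k-group log-rank
#' chi-square test of equal survival.
#'
#' @param groups Named vector (names = sample ids) of group labels.
#' @param clinical `data.frame` with columns `sample`, `os_time` (days),
#'   `os_event` (0/1).
#' @return List with `fit` (a [survival::survfit] object), `chisq`, `df`,
#'   `p` and `n` per group. With no events anywhere, `p` is `NA` and
#'   `flagged` is `TRUE`.
#' @export
kmLogrank <- function(groups, clinical) {
    clinical <- checkClinical(clinical)
    common <- intersect(names(groups), clinical$sample)
    if (length(unique(groups[common])) < 2L)
        stop("need at least 2 groups with clinical data")
    cl <- clinical[match(common, clinical$sample), ]
    grp <- factor(groups[common])
    surv <- survival::Surv(cl$os_time, cl$os_event)
    fit <- survival::survfit(surv ~ grp)
    if (sum(cl$os_event) == 0) {
        message("no events observed; log-rank p undefined")
        return(list(fit = fit, chisq = NA_real_, df = nlevels(grp) - 1L,
                    p = NA_real_, n = table(grp), flagged = TRUE))
    }
    sd <- survival::survdiff(surv ~ grp)
    df <- nlevels(grp) - 1L
    list(fit = fit, chisq = sd$chisq, df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
         n = table(grp), flagged = FALSE)
}

#' Per-gene univariate Cox screen
#'
#' Fits a proportional-hazards model with each gene's expression as a
#' single continuous covariate (partial likelihood, Breslow tie handling),
#' takes the Wald p-value, and adjusts across the full screened list with
#' Benjamini-Hochberg. Genes whose covariate is constant get coefficient 0
#' and p = 1; non-converging fits are flagged with p = 1.
#'
#' @param expr Expression matrix (genes x samples), typically on the VST
#'   scale.
#' @param clinical Clinical table (see [kmLogrank()]).
#' @param fdrMax FDR threshold for the `significant` flag (default 0.05).
#' @return `data.frame` with `gene_id`, `coef` (log hazard ratio per
#'   expression unit), `p_value`, `fdr`, `flagged`, `significant`.
#' @export
coxScreen <- function(expr, clinical, fdrMax = 0.05) {
    clinical <- checkClinical(clinical)
    common <- intersect(colnames(expr), clinical$sample)
    if (length(common) < 3L) stop("too few samples matched to clinical")
    cl <- clinical[match(common, clinical$sample), ]
    surv <- survival::Surv(cl$os_time, cl$os_event)
    ex <- expr[, common, drop = FALSE]
    n <- nrow(ex)
    coefs <- numeric(n); pv <- rep(1, n); flagged <- logical(n)
    for (i in seq_len(n)) {
        x <- ex[i, ]
        if (stats::var(x) == 0) { flagged[i] <- TRUE; next }
        fit <- tryCatch(
            survival::coxph(surv ~ x, ties = "breslow"),
            error = function(e) NULL,
            warning = function(w) NULL)
        if (is.null(fit) || is.na(stats::coef(fit))) {
            flagged[i] <- TRUE
            next
        }
        s <- summary(fit)
        coefs[i] <- unname(stats::coef(fit))
        pv[i] <- s$coefficients[1L, "Pr(>|z|)"]
    }
    fdr <- bhAdjust(pv)
    data.frame(gene_id = rownames(ex), coef = coefs, p_value = pv,
               fdr = fdr, flagged = flagged,
               significant = fdr < fdrMax,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Median dichotomization of one gene's expression
#'
#' Splits samples into `"high"` (strictly above the median) and `"low"`
#' (at or below), the convention used to draw two-group Kaplan-Meier
#' curves per gene. An all-equal profile yields all-`"low"` and is flagged
#' via `attr(, "degenerate")`.
#'
#' @param x Named numeric vector (one expression row).
#' @param rule Cutpoint rule; only `"median"` is implemented.
#' @return Named character vector of `"high"`/`"low"`.
#' @export
dichotomizeExpression <- function(x, rule = c("median")) {
    rule <- match.arg(rule)
    m <- stats::median(x)
    grp <- ifelse(x > m, "high", "low")
    names(grp) <- names(x)
    if (all(grp == "low")) {
        message("degenerate profile: all samples at or below the median")
        attr(grp, "degenerate") <- TRUE
    }
    grp
}
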