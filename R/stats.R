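#' @include AllClasses.R
NULL

#' One-way ANOVA of a longitudinal parameter table
#'
#' Longitudinal structural-parameter records (one value per batch, sample,
#' day and parameter) are compared either across culture time or across
#' batches:
#' \itemize{
#'   \item \code{factor = "time"}: one-way repeated-measures ANOVA with day
#'     as the within-subject factor; the subject is the (batch, sample)
#'     pair. The design must be complete (every subject measured on every
#'     day) or an error names the missing cells.
#'   \item \code{factor = "batch"}: one-way between-groups ANOVA on the
#'     values.
#' }
#' Fitting is delegated to \code{\link[stats]{aov}}; the F ratio, its
#' degrees of freedom and the upper-tail p value are returned.
#'
#' @param table data.frame with columns \code{batch}, \code{sample},
#'   \code{day}, \code{parameter}, \code{value}; the (batch, sample, day,
#'   parameter) key must be unique.
#' @param factor \code{"time"} or \code{"batch"}.
#' @param parameter which parameter to analyse (e.g. \code{"Ra"},
#'   \code{"Th"}); must match the \code{parameter} column.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
#' @examples
#' tab <- expand.grid(batch = 1, sample = 1:5, day = c(1, 5, 9, 13))
#' tab$parameter <- "Ra"
#' tab$value <- rnorm(nrow(tab), mean = tab$day / 5)
#' anovaF(tab, "time", "Ra")
anovaF <- function(table, factor = c("time", "batch"), parameter) {
  factor <- match.arg(factor)
  need <- c("batch", "sample", "day", "parameter", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  tab <- table[table$parameter == parameter & !is.na(table$value), , drop = FALSE]
  if (!nrow(tab))
    stop("no rows for parameter '", parameter, "'")
  key <- interaction(tab$batch, tab$sample, tab$day, drop = TRUE)
  if (anyDuplicated(key))
    stop("(batch, sample, day, parameter) keys must be unique")

  if (factor == "batch") {
    g <- base::factor(tab$batch)
    if (nlevels(g) < 2L) stop("need at least 2 batches")
    if (any(tabulate(g) < 2L)) stop("need at least 2 observations per batch")
    sm <- summary(aov(tab$value ~ g))[[1L]]
    Fv <- sm[["F value"]][1L]
    return(list(F = Fv, df1 = sm$Df[1L], df2 = sm$Df[2L],
                p = sm[["Pr(>F)"]][1L]))
  }

  subj <- base::factor(paste(tab$batch, tab$sample, sep = "/"))
  dayF <- base::factor(tab$day)
  if (nlevels(dayF) < 2L) stop("need at least 2 days")
  grid <- base::table(subj, dayF)
  if (any(grid != 1L)) {
    bad <- which(grid == 0L, arr.ind = TRUE)
    cells <- apply(bad, 1L, function(i)
      sprintf("subject %s on day %s", rownames(grid)[i[1]], colnames(grid)[i[2]]))
    stop("incomplete repeated-measures design; missing cell(s): ",
         paste(cells, collapse = "; "))
  }
  fit <- aov(tab$value ~ dayF + Error(subj))
  sm <- summary(fit)[["Error: Within"]][[1L]]
  list(F = sm[["F value"]][1L], df1 = sm$Df[1L], df2 = sm$Df[2L],
       p = sm[["Pr(>F)"]][1L])
}

#' Upper-tail probability of the F distribution
#'
#' Returns \code{P(F(df1, df2) > F)}, the p value attached to a printed
#' ANOVA F statistic, so reported (F, df) pairs can be checked directly.
#'
#' @param F observed statistic, >= 0.
#' @param df1,df2 numerator and denominator degrees of freedom, >= 1.
#' @return the upper-tail probability in (0, 1].
#' @export
#' @examples
#' fTailProbability(77.019, 3, 10)   # ~3.27e-7
fTailProbability <- function(F, df1, df2) {
  if (!is.finite(F) || F < 0) stop("'F' must be a non-negative number")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  pf(F, df1, df2, lower.tail = FALSE)
}
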