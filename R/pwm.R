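#' @include AllClasses.R AllGenerics.R
NULL

.aaIndex <- function(peptide, onNonstandard = c("error", "skip")) {
  onNonstandard <- match.arg(onNonstandard)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA20)
  if (anyNA(idx) && onNonstandard == "error")
    stop("non-standard residue(s) in peptide: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx
}

#' Build a PWM from raw per-position amino-acid counts
#'
#' Converts a nonnegative count matrix (positions x 20 amino acids) into an
#' adjusted probability profile using Henikoff position-based pseudocounts:
#' \deqn{m(p,aa) = \frac{n(p,aa) + B_p b_{aa}}{N_p + B_p}} with a uniform
#' background \eqn{b_{aa} = 1/20} and \eqn{B_p = 5 R_p}, where \eqn{R_p} is
#' the number of distinct residues observed at position \eqn{p}. Every
#' adjusted entry is strictly positive and each position sums to one. The
#' optimal binding score is the sum over positions of the adjusted maxima, so
#' the consensus peptide scores exactly 1 after normalization
#' (see [scoreSite()]).
#'
#' @param counts numeric matrix, rows = ligand positions, 20 columns. Columns
#'   may be named with the standard amino acids in any order; unnamed columns
#'   are taken alphabetical.
#' @param classId character identifier of the specificity class.
#' @return A [PWM-class] object.
#' @export
#' @examples
#' counts <- matrix(0, 1, 20, dimnames = list(NULL, NetRewire:::AA20))
#' counts[1, "R"] <- 8   # single observed residue: R_p = 1, B_p = 5
#' p <- buildPWM(counts, "toy")
#' pwmProfile(p)[1, "R"] # (8 + 0.25) / (8 + 5)
buildPWM <- function(counts, classId = "pwm") {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L) stop("counts needs >= 1 position")
  if (ncol(counts) != 20L) stop("counts needs 20 amino-acid columns")
  if (is.null(colnames(counts))) colnames(counts) <- AA20
  if (!setequal(colnames(counts), AA20))
    stop("count columns must be the 20 standard amino acids")
  counts <- counts[, AA20, drop = FALSE]
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0))
    stop("all-zero count column (position with no observations)")

  Rp <- rowSums(counts > 0)            # distinct residues observed
  Bp <- 5 * Rp
  Np <- rowSums(counts)
  profile <- (counts + Bp * (1 / 20)) / (Np + Bp)
  dimnames(profile) <- list(NULL, AA20)

  consensus <- paste(AA20[apply(profile, 1L, which.max)], collapse = "")
  new("PWM",
      classId = as.character(classId),
      counts = counts,
      profile = profile,
      optimalScore = sum(apply(profile, 1L, max)),
      consensus = consensus)
}

#' Raw counts encoding a consensus motif
#'
#' Convenience builder for simulations and examples: each position gets
#' `strength` counts on the consensus residue ("X" means no preference:
#' one count on every residue) plus one count on `nAlt` other residues.
#'
#' @param consensus character motif; "X" positions are unconstrained.
#' @param strength counts placed on the consensus residue.
#' @param nAlt number of alternative residues receiving one count each.
#' @return A counts matrix suitable for [buildPWM()].
#' @export
consensusCounts <- function(consensus, strength = 18, nAlt = 2) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  counts <- matrix(0, length(chars), 20L, dimnames = list(NULL, AA20))
  for (p in seq_along(chars)) {
    if (chars[p] == "X") {
      counts[p, ] <- 1
    } else {
      if (!chars[p] %in% AA20) stop("non-standard consensus residue: ", chars[p])
      counts[p, chars[p]] <- strength
      alt <- setdiff(AA20, chars[p])[seq_len(nAlt)]
      counts[p, alt] <- 1
    }
  }
  counts
}

#' Score one peptide against a PWM
#'
#' The binding-site score is the additive profile sum normalized by the
#' optimal binding score, \deqn{score = S(peptide)/S_{opt}, \quad S =
#' \sum_p m(p, aa_p),} so scores lie in (0, 1] and the consensus peptide
#' scores exactly 1.
#'
#' @param pwm a [PWM-class].
#' @param peptide character of length `pwmLength(pwm)`.
#' @return numeric score in (0, 1].
#' @export
#' @examples
#' p <- buildPWM(consensusCounts("RAP"), "toy")
#' scoreSite(p, consensusSeq(p))  # exactly 1
scoreSite <- function(pwm, peptide) {
  stopifnot(is(pwm, "PWM"))
  n <- pwmLength(pwm)
  if (nchar(peptide) != n)
    stop("peptide length ", nchar(peptide), " != PWM length ", n)
  idx <- .aaIndex(peptide, "error")
  sum(pwm@profile[cbind(seq_len(n), idx)]) / pwm@optimalScore
}

#' Scan a protein sequence with a PWM
#'
#' Scores every window of the sequence and attaches the mean disorder and
#' surface-accessibility track values over the window residues. Coordinates
#' are 0-based half-open. Sequences shorter than the PWM yield an empty
#' table; with `onNonstandard = "skip"`, windows containing non-standard
#' residues are dropped rather than raising an error.
#'
#' @param pwm a [PWM-class].
#' @param sequence character protein sequence (or an `Biostrings::AAString`).
#' @param disorder,accessibility numeric per-residue tracks, same length as
#'   the sequence (recycled as constant if length 1).
#' @param target name of the protein (carried into the output).
#' @param species species label (carried into the output).
#' @param onNonstandard "error" (default) or "skip".
#' @return data.frame of scored sites sorted by score descending, columns
#'   `species`, `target_protein`, `class_id`, `start`, `end`, `peptide`,
#'   `score`, `disorder`, `accessibility`.
#' @export
scanProtein <- function(pwm, sequence, disorder = 0, accessibility = 0,
                        target = "protein", species = "species",
                        onNonstandard = c("error", "skip")) {
  onNonstandard <- match.arg(onNonstandard)
  stopifnot(is(pwm, "PWM"))
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  n <- pwmLength(pwm)
  if (length(disorder) == 1L) disorder <- rep(disorder, L)
  if (length(accessibility) == 1L) accessibility <- rep(accessibility, L)
  if (length(disorder) != L || length(accessibility) != L)
    stop("track lengths must equal the sequence length")
  empty <- data.frame(species = character(), target_protein = character(),
                      class_id = character(), start = integer(),
                      end = integer(), peptide = character(),
                      score = numeric(), disorder = numeric(),
                      accessibility = numeric())
  if (L < n) return(empty)

  idx <- .aaIndex(sequence, onNonstandard)
  nw <- L - n + 1L
  starts <- seq_len(nw)                       # 1-based window starts
  scores <- numeric(nw)
  for (p in seq_len(n)) {
    col <- idx[starts + p - 1L]
    v <- pwm@profile[p, ]
    scores <- scores + ifelse(is.na(col), NA_real_, v[col])
  }
  keep <- !is.na(scores)
  if (!any(keep)) return(empty)
  starts <- starts[keep]
  scores <- scores[keep] / pwm@optimalScore
  # mean track values over window residues via cumulative sums
  cd <- cumsum(c(0, disorder)); ca <- cumsum(c(0, accessibility))
  dis <- (cd[starts + n] - cd[starts]) / n
  acc <- (ca[starts + n] - ca[starts]) / n
  out <- data.frame(
    species = species, target_protein = target, class_id = pwm@classId,
    start = starts - 1L, end = starts - 1L + n,
    peptide = substring(sequence, starts, starts + n - 1L),
    score = scores, disorder = dis, accessibility = acc,
    stringsAsFactors = FALSE)
  out[order(-out$score, out$start), , drop = FALSE]
}

#' Scan a whole proteome with a set of PWMs
#'
#' Applies [scanProtein()] to every (PWM, protein) pair and binds the
#' results. Tracks are supplied as a list per protein (`$disorder`,
#' `$accessibility`) or default to constants.
#'
#' @param pwms list of [PWM-class] objects.
#' @param proteome named character vector or `Biostrings::AAStringSet`.
#' @param tracks optional named list per protein with numeric `disorder` and
#'   `accessibility` vectors.
#' @param species species label.
#' @param onNonstandard passed to [scanProtein()].
#' @return data.frame of all scored sites.
#' @export
scanProteome <- function(pwms, proteome, tracks = NULL, species = "species",
                         onNonstandard = c("error", "skip")) {
  onNonstandard <- match.arg(onNonstandard)
  seqs <- as.character(proteome)
  if (is.null(names(seqs))) stop("proteome sequences must be named")
  res <- vector("list", length(pwms) * length(seqs))
  k <- 0L
  for (pwm in pwms) {
    for (id in names(seqs)) {
      tr <- tracks[[id]]
      k <- k + 1L
      res[[k]] <- scanProtein(
        pwm, seqs[[id]],
        disorder = if (is.null(tr)) 0 else tr$disorder,
        accessibility = if (is.null(tr)) 0 else tr$accessibility,
        target = id, species = species, onNonstandard = onNonstandard)
    }
  }
  do.call(rbind, res)
}

#' Total information-content entropy of a PWM
#'
#' Sum over positions of the Shannon entropy (base 2) of the adjusted
#' column distribution. A maximally uninformative PWM of length N scores
#' `N * log2(20)` bits; sharper columns score lower.
#'
#' @param pwm a [PWM-class].
#' @return numeric, bits.
#' @export
pwmEntropy <- function(pwm) {
  stopifnot(is(pwm, "PWM"))
  prof <- pwm@profile
  -sum(prof * log2(prof))
}

#' Dissimilarity between two PWMs of possibly different lengths
#'
#' Each profile is padded on both flanks with columns of a fake amino acid
#' "X" (a 21st alphabet letter: padded columns put probability 1 on X, real
#' columns have 0 there) so the two matrices can be slid across all relative
#' offsets. For each offset the per-position L2 distances of aligned columns
#' are averaged over the union span; the dissimilarity is the minimum over
#' offsets. Symmetric, and zero exactly for identical profiles.
#'
#' @param a,b [PWM-class] objects.
#' @return numeric dissimilarity >= 0.
#' @export
pwmDissimilarity <- function(a, b) {
  stopifnot(is(a, "PWM"), is(b, "PWM"))
  # columns in 21 dimensions; dimension 21 is the fake letter X
  ext <- function(p) rbind(t(p), 0)
  padcol <- c(rep(0, 20), 1)
  A <- ext(a@profile); B <- ext(b@profile)
  la <- ncol(A); lb <- ncol(B)
  best <- Inf
  for (s in seq(-(lb - 1L), la - 1L)) {      # offset of B's first column
    lo <- min(0L, s); hi <- max(la - 1L, s + lb - 1L)
    pos <- lo:hi
    tot <- 0
    for (p in pos) {
      ca <- if (p >= 0L && p < la) A[, p + 1L] else padcol
      cb <- if (p >= s && p < s + lb) B[, p - s + 1L] else padcol
      tot <- tot + sqrt(sum((ca - cb)^2))
    }
    best <- min(best, tot / length(pos))
  }
  best
}

#' Upper-tail p-value of a best score against a fitted t background
#'
#' Fits a location/scale Student t distribution (df = n - 1, location =
#' sample mean, scale = sample sd) to a background of per-protein best
#' scores and returns the upper-tail probability of the observed score.
#'
#' @param bestScores numeric background scores (>= 3 values).
#' @param observed numeric, the score to test.
#' @return numeric p-value in (0, 1).
#' @export
backgroundPValue <- function(bestScores, observed) {
  n <- length(bestScores)
  if (n < 3L) stop("need >= 3 background scores")
  s <- stats::sd(bestScores)
  if (s == 0) stop("zero-variance background")
  stats::pt((observed - mean(bestScores)) / s, df = n - 1, lower.tail = FALSE)
}

#' Read / write PWM TSV files
#'
#' The on-disk format is a TSV with two header comment lines
#' (`#class_id=<id>` and `#type=counts`), rows = ligand positions and the 20
#' standard amino acids as columns.
#'
#' @param path file path.
#' @return `readPWM` returns a [PWM-class]; `writePWM` returns `path`
#'   invisibly.
#' @export
readPWM <- function(path) {
  hdr <- readLines(path, n = 2L)
  cid <- sub("^#class_id=", "", hdr[grepl("^#class_id=", hdr)][1L])
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  buildPWM(as.matrix(tab), classId = cid)
}

#' @rdname readPWM
#' @param pwm a [PWM-class] to write.
#' @export
writePWM <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#class_id=", pwm@classId), "#type=counts"), con)
  utils::write.table(as.data.frame(pwm@counts), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
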