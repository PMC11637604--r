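# Pedigree representation
#
# A pedigree is a data.frame with columns id, sire, dam (NA = unknown) and
# sex ("M"/"F"), stored in topological order (parents before offspring) with
# a derived `founder` column. All downstream machinery (A, A-inverse,
# breeding-value simulation) relies on that ordering.

new_pedigree <- function(df, reordered = FALSE) {
  df$founder <- is.na(df$sire) & is.na(df$dam)
  rownames(df) <- NULL
  structure(df, class = c("pedigree", "data.frame"), reordered = reordered)
}

#' @export
print.pedigree <- function(x, n = 6L, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders, %d M / %d F)\n",
              nrow(x), sum(x$founder), sum(x$sex == "M"), sum(x$sex == "F")))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

# Kahn topological sort; raises ige_pedigree_cycle when no order exists
# (self-ancestry included).
topo_sort_pedigree <- function(df) {
  n <- nrow(df)
  idx <- match(df$id, df$id)
  sire_i <- match(df$sire, df$id)
  dam_i <- match(df$dam, df$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    # pop the smallest original index for a deterministic order
    i <- queue[1]
    queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(order) < n)
    ige_error("ige_pedigree_cycle",
              "pedigree contains a cycle (an individual is its own ancestor)")
  order
}

validate_pedigree <- function(df) {
  if (anyDuplicated(df$id))
    ige_error("ige_duplicate_id",
              paste("duplicate individual id(s):",
                    paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  sires <- unique(df$sire[!is.na(df$sire)])
  dams <- unique(df$dam[!is.na(df$dam)])
  both <- intersect(sires, dams)
  if (length(both))
    ige_error("ige_sex_inconsistency",
              paste("id(s) used both as sire and as dam:",
                    paste(both, collapse = ", ")))
  missing_par <- setdiff(c(sires, dams), df$id)
  if (length(missing_par))
    ige_error("ige_undefined_parent",
              paste("parent id(s) referenced but never defined:",
                    paste(missing_par, collapse = ", ")))
  bad_sire <- sires[df$sex[match(sires, df$id)] != "M"]
  if (length(bad_sire))
    ige_error("ige_sex_inconsistency",
              paste("sire(s) not recorded as male:", paste(bad_sire, collapse = ", ")))
  bad_dam <- dams[df$sex[match(dams, df$id)] != "F"]
  if (length(bad_dam))
    ige_error("ige_sex_inconsistency",
              paste("dam(s) not recorded as female:", paste(bad_dam, collapse = ", ")))
  invisible(df)
}

#' Construct a pedigree from id/sire/dam/sex vectors
#'
#' Unknown parents are encoded as `NA`, `""` or `"0"`. The pedigree is
#' validated (unique ids, parents defined, sexes consistent with parental
#' roles, no ancestry cycles) and topologically sorted so that every parent
#' precedes its offspring.
#'
#' @param id,sire,dam,sex character vectors of equal length; `sex` uses
#'   `"M"`/`"F"`.
#' @return a `pedigree` object (a data.frame with columns `id`, `sire`,
#'   `dam`, `sex`, `founder`).
#' @export
pedigree <- function(id, sire, dam, sex) {
  as_unknown <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA") | is.na(x)] <- NA_character_
    x
  }
  df <- data.frame(id = as.character(id), sire = as_unknown(sire),
                   dam = as_unknown(dam), sex = toupper(as.character(sex)),
                   stringsAsFactors = FALSE)
  if (!all(df$sex %in% c("M", "F")))
    ige_error("ige_bad_sex", "sex must be 'M' or 'F'")
  validate_pedigree(df)
  ord <- topo_sort_pedigree(df)
  new_pedigree(df[ord, ], reordered = !identical(ord, seq_len(nrow(df))))
}

#' Read a pedigree from a CSV file or connection
#'
#' Expects columns `id`, `sire`, `dam`, `sex` with unknown parents coded as
#' `"0"` or empty. Rows are re-sorted into topological order if necessary
#' (recorded in the `reordered` attribute, with a message).
#'
#' @param source path or connection readable by [utils::read.csv()].
#' @return a validated `pedigree`.
#' @export
read_pedigree <- function(source) {
  df <- read.csv(source, colClasses = "character")
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(df)))
    ige_error("ige_bad_header",
              paste("pedigree file must have columns", paste(need, collapse = ", ")))
  ped <- pedigree(df$id, df$sire, df$dam, df$sex)
  if (isTRUE(attr(ped, "reordered")))
    message("pedigree rows were not in topological order; re-sorted on read")
  ped
}

#' Write a pedigree to CSV
#'
#' Inverse of [read_pedigree()]; unknown parents are emitted as `"0"`.
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = ped$sex)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a paternal half-sib breeding design
#'
#' Builds the pedigree of a classic paternal half-sib design: `n_sires`
#' unrelated sires each mated to `dams_per_sire` unrelated dams, every
#' surviving full-sib family contributing `offspring_per_family` offspring.
#' Breeding failures are independent Bernoulli events removing whole
#' families, which is how a nominal 35 x 2 design ends up with fewer
#' realised families.
#'
#' @param n_sires number of sires (founder males).
#' @param dams_per_sire dams mated to each sire.
#' @param offspring_per_family offspring per surviving full-sib family.
#' @param family_failure_rate probability that a mating produces no family.
#' @param prop_female probability that an offspring is female; offspring
#'   sexes are drawn independently.
#' @param seed integer seed; the pedigree is deterministic given the seed.
#' @return a `pedigree`; founders are all unrelated and non-inbred.
#' @export
build_half_sib_design <- function(n_sires, dams_per_sire, offspring_per_family,
                                  family_failure_rate = 0, prop_female = 0.5,
                                  seed = 1L) {
  stopifnot(n_sires >= 1, dams_per_sire >= 1, offspring_per_family >= 1,
            family_failure_rate >= 0, family_failure_rate <= 1,
            prop_female >= 0, prop_female <= 1)
  with_seed(seed, {
    sires <- sprintf("S%03d", seq_len(n_sires))
    dams <- sprintf("D%03d", seq_len(n_sires * dams_per_sire))
    fam_sire <- rep(sires, each = dams_per_sire)
    fam_dam <- dams
    survive <- runif(length(fam_dam)) >= family_failure_rate
    ids <- c(sires, dams)
    sire_col <- rep(NA_character_, length(ids))
    dam_col <- rep(NA_character_, length(ids))
    sex_col <- c(rep("M", length(sires)), rep("F", length(dams)))
    k <- 0L
    for (f in which(survive)) {
      for (o in seq_len(offspring_per_family)) {
        k <- k + 1L
        ids <- c(ids, sprintf("O%05d", k))
        sire_col <- c(sire_col, fam_sire[f])
        dam_col <- c(dam_col, fam_dam[f])
        sex_col <- c(sex_col, if (runif(1) < prop_female) "F" else "M")
      }
    }
    pedigree(ids, sire_col, dam_col, sex_col)
  })
}

#' Number of realised full-sib families in a pedigree
#'
#' @param ped a `pedigree`.
#' @return count of distinct (sire, dam) pairs with offspring.
#' @export
n_families <- function(ped) {
  off <- !ped$founder
  length(unique(paste(ped$sire[off], ped$dam[off])))
}
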