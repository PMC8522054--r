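# Pedigree construction, PED/status I/O, and validation.
#
# A pedigree is a data.frame (class "twohit_pedigree") with one row per
# individual: sample, family, father, mother ("0" = not enrolled), sex
# (1 = male, 2 = female), role (grandparent/parent/child), carrier (0/1 for
# the primary deletion).

new_pedigree <- function(df) {
  need <- c("sample", "family", "father", "mother", "sex", "role", "carrier")
  if (!all(need %in% names(df)))
    stop_twohit("pedigree is missing columns: ",
                paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[, need]
  df$sample <- as.character(df$sample)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  validate_pedigree(df)
  class(df) <- c("twohit_pedigree", "data.frame")
  df
}

validate_pedigree <- function(df) {
  if (anyDuplicated(df$sample))
    stop_twohit("duplicated sample ids in pedigree")
  known <- c("0", df$sample)
  bad <- setdiff(c(df$father, df$mother), known)
  if (length(bad))
    stop_twohit("parent ids absent from pedigree: ",
                paste(unique(bad), collapse = ", "))
  if (!all(df$carrier %in% c(0L, 1L)))
    stop_twohit("carrier status must be 0/1")
  # cycle check: walking up parent links must terminate
  up <- function(id, seen) {
    if (id == "0") return(invisible(NULL))
    if (id %in% seen) stop_twohit("cyclic parentage at sample ", id)
    row <- df[df$sample == id, ]
    up(row$father, c(seen, id))
    up(row$mother, c(seen, id))
  }
  for (id in df$sample) up(id, character(0))
  invisible(df)
}

# Default five-family cohort layout: 32 individuals, 19 deletion carriers and
# 13 noncarriers; 10 carrier children; six carrier x noncarrier parent pairs
# (one family with two pairs); three grandparent pairs; four noncarrier
# siblings.  One carrier child has an unenrolled second parent, so 9 carrier
# children and 4 carrier parents yield 13 complete trios.
default_family_structures <- function() {
  fam <- function(...) {
    df <- do.call(rbind, lapply(list(...), function(m)
      data.frame(id = m[[1]], father = m[[2]], mother = m[[3]],
                 role = m[[4]], carrier = as.integer(m[[5]]),
                 stringsAsFactors = FALSE)))
    df
  }
  list(
    fam(list("GP1", "0", "0", "grandparent", 1),
        list("GP2", "0", "0", "grandparent", 0),
        list("P1", "GP1", "GP2", "parent", 1),
        list("S1", "0", "0", "parent", 0),
        list("P2", "GP1", "GP2", "parent", 1),
        list("S2", "0", "0", "parent", 0),
        list("C1", "P1", "S1", "child", 1),
        list("C2", "P1", "S1", "child", 1),
        list("C3", "P2", "S2", "child", 1),
        list("N1", "P2", "S2", "child", 0)),
    fam(list("GP1", "0", "0", "grandparent", 1),
        list("GP2", "0", "0", "grandparent", 0),
        list("P1", "GP1", "GP2", "parent", 1),
        list("S1", "0", "0", "parent", 0),
        list("C1", "P1", "S1", "child", 1),
        list("C2", "P1", "S1", "child", 1),
        list("N1", "P1", "S1", "child", 0)),
    fam(list("GP1", "0", "0", "grandparent", 1),
        list("GP2", "0", "0", "grandparent", 0),
        list("P1", "GP1", "GP2", "parent", 1),
        list("S1", "0", "0", "parent", 0),
        list("C1", "P1", "S1", "child", 1),
        list("C2", "P1", "S1", "child", 1),
        list("N1", "P1", "S1", "child", 0)),
    fam(list("P1", "0", "0", "parent", 1),
        list("S1", "0", "0", "parent", 0),
        list("C1", "P1", "S1", "child", 1),
        list("C2", "P1", "S1", "child", 1)),
    # carrier child C1 has an unenrolled second parent; N1 is a noncarrier
    # sibling with both parents enrolled
    fam(list("P1", "0", "0", "parent", 1),
        list("S1", "0", "0", "parent", 0),
        list("C1", "P1", "0", "child", 1),
        list("N1", "P1", "S1", "child", 0))
  )
}

#' Simulate a multi-generation family cohort pedigree
#'
#' Instantiates the pedigree templates in `spec$family_structures` (by
#' default a five-family, 32-individual layout with 19 deletion carriers,
#' 13 noncarriers and three grandparent pairs).  Structure and carrier
#' transmission are taken from the templates; only sexes of non-paired
#' individuals are drawn at random.
#'
#' @param spec a [cohort_spec()].
#' @return a `twohit_pedigree` data.frame.
#' @examples
#' ped <- simulate_pedigree(cohort_spec(seed = 1))
#' table(ped$carrier)
#' @export
simulate_pedigree <- function(spec = cohort_spec()) {
  structures <- spec$family_structures
  if (!is.list(structures) || !length(structures))
    stop_twohit("spec$family_structures must be a non-empty list of templates")
  with_seed(derive_seed(spec$seed, "pedigree"), {
    rows <- list()
    for (f in seq_along(structures)) {
      tmpl <- structures[[f]]
      need <- c("id", "father", "mother", "role", "carrier")
      if (!is.data.frame(tmpl) || !all(need %in% names(tmpl)))
        stop_twohit("invalid pedigree structure template in family ", f)
      famid <- sprintf("F%d", f)
      qual <- function(id) ifelse(id == "0", "0", paste0(famid, ".", id))
      # fathers male, mothers female; everyone else drawn at random
      sex <- ifelse(tmpl$id %in% tmpl$father, 1L,
             ifelse(tmpl$id %in% tmpl$mother, 2L,
                    sample(c(1L, 2L), nrow(tmpl), replace = TRUE)))
      rows[[f]] <- data.frame(
        sample = qual(tmpl$id), family = famid,
        father = qual(tmpl$father), mother = qual(tmpl$mother),
        sex = sex, role = tmpl$role, carrier = as.integer(tmpl$carrier),
        stringsAsFactors = FALSE)
    }
    ped <- do.call(rbind, rows)
    # ensure father/mother slots are used consistently: if a referenced
    # father drew sex 2 (or mother sex 1), fix it
    ped$sex[ped$sample %in% ped$father] <- 1L
    ped$sex[ped$sample %in% ped$mother] <- 2L
    ped <- new_pedigree(ped)
    for (famid in unique(ped$family)) {
      fp <- ped[ped$family == famid & ped$role %in% c("parent", "grandparent"), ]
      if (!any(fp$carrier == 1L) || !any(fp$carrier == 0L))
        stop_twohit("family ", famid,
                    " lacks a carrier x noncarrier parent pair")
    }
    ped
  })
}

#' Write a pedigree as PED + status files
#'
#' Emits a 6-column PED file (family, sample, father, mother, sex, phenotype;
#' phenotype = carrier status + 1) and a `status.tsv` with columns
#' `sample_id`, `deletion_carrier`, `role`.
#'
#' @param ped a `twohit_pedigree`.
#' @param ped_path,status_path output paths.
#' @return invisibly, `ped_path`.
#' @export
write_pedigree <- function(ped, ped_path, status_path) {
  peddf <- data.frame(ped$family, ped$sample, ped$father, ped$mother,
                      ped$sex, ped$carrier + 1L)
  write.table(peddf, ped_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(data.frame(sample_id = ped$sample,
                       deletion_carrier = ped$carrier,
                       role = ped$role), status_path)
  invisible(ped_path)
}

#' Parse PED and carrier-status files into a pedigree
#'
#' @param ped_path 6-column PED file (no header).
#' @param status_path TSV with columns `sample_id`, `deletion_carrier`,
#'   `role`; every PED sample must be present.
#' @return a `twohit_pedigree`.
#' @export
parse_pedigree <- function(ped_path, status_path) {
  p <- read.table(ped_path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE,
                  col.names = c("family", "sample", "father", "mother",
                                "sex", "phenotype"))
  if (ncol(p) != 6L) stop_twohit("PED file must have 6 columns")
  s <- read_tsv(status_path)
  if (!all(c("sample_id", "deletion_carrier", "role") %in% names(s)))
    stop_twohit("status file must have sample_id, deletion_carrier, role")
  missing <- setdiff(p$sample, s$sample_id)
  if (length(missing))
    stop_twohit("status file is missing samples: ",
                paste(missing, collapse = ", "))
  i <- match(p$sample, s$sample_id)
  new_pedigree(data.frame(
    sample = as.character(p$sample), family = as.character(p$family),
    father = as.character(p$father), mother = as.character(p$mother),
    sex = p$sex, role = s$role[i],
    carrier = as.integer(s$deletion_carrier[i]),
    stringsAsFactors = FALSE))
}
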