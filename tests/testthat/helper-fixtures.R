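# In-code fixtures shared across test files.

# A small well-formed report tibble; n distinct reports.
make_reports <- function(n = 10) {
  tibble::tibble(
    report_id = sprintf("T%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = 40 + seq_len(n),
    age_unit = "years",
    country = rep(c("US", "JP"), length.out = n),
    event_date = as.Date("2020-01-01") + seq_len(n),
    therapy_start_date = as.Date("2019-12-01") + seq_len(n),
    drug_name = rep(c("bevacizumab", "sunitinib", "aspirin"),
                    length.out = n),
    drug_role = "primary_suspect",
    indication = rep(c("Hepatocellular carcinoma", "Colorectal cancer",
                       "Macular degeneration"), length.out = n),
    reactions = lapply(seq_len(n), function(i) {
      if (i %% 2 == 0) c("Hypertension", "Nausea") else "Fatigue"
    })
  )
}

make_report_set <- function(n = 10) report_set(make_reports(n))

# A report set with exactly the given contingency cells for
# (drug = "bevacizumab", pt = "Hypertension").
make_cell_reports <- function(a, b, c, d) {
  n <- a + b + c + d
  drug <- c(rep("bevacizumab", a + b), rep("aspirin", c + d))
  pt <- c(rep("Hypertension", a), rep("Nausea", b),
          rep("Hypertension", c), rep("Nausea", d))
  report_set(tibble::tibble(
    report_id = sprintf("C%05d", seq_len(n)),
    sex = "male", age = seq_len(n), age_unit = "years", country = "US",
    event_date = as.Date("2020-06-01"),
    therapy_start_date = as.Date("2020-05-01"),
    drug_name = drug, drug_role = "primary_suspect",
    indication = "Colorectal cancer",
    reactions = as.list(pt)
  ))
}

# FAERS quarterly ASCII fixture written to a temp directory; returns the
# named path list. One DEMO row has an unparseable event date, one
# primaryid has no REAC rows.
write_faers_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  demo <- c("primaryid$caseid$sex$age$age_cod$occr_country$event_dt",
            "1001$1$M$61$YR$US$20200315",
            "1002$2$F$55$YR$JP$NOTADATE",
            "1003$3$UNK$70$YR$FR$20210101")
  drug <- c("primaryid$drugname$role_cod",
            "1001$BEVACIZUMAB$PS",
            "1002$SUNITINIB$PS",
            "1003$ASPIRIN$SS")
  reac <- c("primaryid$pt",
            "1001$Hypertension",
            "1001$Nausea",
            "1002$Blood pressure increased")
  indi <- c("primaryid$indi_pt",
            "1001$Colorectal cancer",
            "1002$Renal cell carcinoma")
  ther <- c("primaryid$start_dt",
            "1001$20200201",
            "1002$20200110")
  paths <- list(demo = file.path(dir, "DEMO.txt"),
                drug = file.path(dir, "DRUG.txt"),
                reac = file.path(dir, "REAC.txt"),
                indi = file.path(dir, "INDI.txt"),
                ther = file.path(dir, "THER.txt"))
  writeLines(demo, paths$demo)
  writeLines(drug, paths$drug)
  writeLines(reac, paths$reac)
  writeLines(indi, paths$indi)
  writeLines(ther, paths$ther)
  paths
}

# Tiny expression fixture: 5 genes, explicit values per sample.
make_expr <- function(values, genes = paste0("g", seq_len(nrow(values))),
                      types = rep("A", ncol(values))) {
  rownames(values) <- genes
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, types, scale = "FPKM")
}
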