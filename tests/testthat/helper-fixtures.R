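# hand-built 10-gene fixture covering every branch of the
# allelic-classification cascade (shared by unit and acceptance tests)
make_fixture <- function() {
  samples <- data.frame(
    sample_id = c("WT_DMSO_c1", "WT_DMSO_c2", "KO_Aza_c1", "KO_Aza_c2"),
    condition = c("WT_DMSO", "WT_DMSO", "KO_Aza", "KO_Aza"),
    clone = c("clone1", "clone2", "clone1", "clone2"))
  # per gene: list of (mus, cas) per sample in the order above, plus fpkm
  g <- list(
    inactive      = list(m = c(5, 5, 5, 5),    c = c(95, 95, 95, 95),
                         fpkm = c(1, 0, 1, 1)),          # FPKM 0 once
    thin          = list(m = c(1, 1, 1, 1),    c = c(11, 30, 30, 30),
                         fpkm = rep(1, 4)),              # 12 reads once
    boundary13    = list(m = c(1, 1, 1, 1),    c = c(12, 12, 12, 12),
                         fpkm = rep(1, 4)),              # exactly 13 reads
    miscalled     = list(m = c(30, 30, 30, 30), c = c(70, 70, 70, 70),
                         fpkm = rep(1, 4)),              # control flags it
    clean_subject = list(m = c(2, 2, 2, 2),    c = c(98, 98, 98, 98),
                         fpkm = rep(1, 4)),
    escapee11     = list(m = c(11, 2, 11, 11), c = c(100, 98, 100, 100),
                         fpkm = rep(1, 4)),              # ratio 0.11 once
    ratio10       = list(m = c(10, 10, 10, 10), c = c(100, 100, 100, 100),
                         fpkm = rep(1, 4)),              # ratio exactly 0.10
    reactivated   = list(m = c(4, 6, 16, 19),  c = c(96, 94, 84, 81),
                         fpkm = rep(1, 4)),              # fold 3.5, p < 0.1
    fold29        = list(m = c(5, 5, 14, 15),  c = c(95, 95, 86, 85),
                         fpkm = rep(1, 4)),              # fold 2.9
    from_zero     = list(m = c(0, 0, 5, 7),    c = c(100, 100, 95, 93),
                         fpkm = rep(1, 4)))              # baseline 0
  rows <- do.call(rbind, lapply(names(g), function(nm) {
    data.frame(gene_id = nm, gene_length_bp = 1e4,
               sample_id = samples$sample_id, condition = samples$condition,
               clone = samples$clone, mus_reads = g[[nm]]$m,
               cas_reads = g[[nm]]$c, fpkm = g[[nm]]$fpkm)
  }))
  ctl <- do.call(rbind, lapply(names(g), function(nm) {
    mus <- if (nm == "miscalled") c(2, 2) else c(0, 9)
    cas <- if (nm == "miscalled") c(18, 18) else c(100, 91)
    data.frame(gene_id = nm, gene_length_bp = 1e4,
               sample_id = c("cas1", "cas2"), condition = "cas_control",
               clone = c("ctl1", "ctl2"), mus_reads = mus, cas_reads = cas,
               fpkm = 1)
  }))
  list(table = rows, control = ctl)
}

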