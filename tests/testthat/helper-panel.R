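# shared fixtures: cached default panel and small builders

.testCache <- new.env(parent = emptyenv())

testPanel <- function() {
    if (is.null(.testCache$panel))
        .testCache$panel <- defaultPanel()
    .testCache$panel
}

# read the bundled config as a plain list for mutation-based tests
panelConfig <- function() {
    yaml::read_yaml(system.file("extdata", "hfe_panel.yaml",
                                package = "hfeRFLP"))
}

loadPanelFromConfig <- function(cfg) {
    path <- withr::local_tempfile(fileext = ".yaml",
                                  .local_envir = parent.frame())
    yaml::write_yaml(cfg, path)
    loadPanel(path)
}

# hand-built peak table: df-like arguments dye/size/height
peakTab <- function(dye, size, height, id = "manual") {
    PeakTable(id, data.frame(dye = dye, size = size, height = height))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
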