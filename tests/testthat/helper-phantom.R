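## A compact phantom used by the unit tests (the default 48^3 spec is for
## the end-to-end checks).
smallPhantomSpec <- function(sigma0 = 0, params = oneTissueParams(0.9, 0.35, 0.05)) {
    phantomSpec(dim = c(24L, 24L, 24L), voxelSize = c(4, 4, 4),
                tumourCentre = c(16, 15, 12), tumourRadius = 8,
                params = params, aortaCentre = c(7, 10), aortaRadius = 4,
                sigma0 = sigma0)
}
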