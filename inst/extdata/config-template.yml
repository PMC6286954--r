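# crownseg configuration template: flat key-value pairs mirroring the CLI
# flags (command-line flags override these values, which override defaults).
# Used as: crownseg segment --config config.yml --bare-dsm bare.asc ...

closing-radius: 50          # diamond radius (px) for scaffold closing
threshold-sensitivity: 0.9  # foreground iff height > sensitivity * local mean
# threshold-window: 901     # odd window (px); default = half the smaller dim
min-area: 25                # min scaffold component area after closing (px)
despeckle-min-area: 64      # min foreground component before closing (px)
connectivity: 8             # component connectivity (4 or 8)
row-angle: 0                # planting-row direction (degrees from col axis)
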