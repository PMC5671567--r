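# Deletion polymorphism esv3587138 (published coordinates, 0-based half-open),
# overlapping the rs7551421 example variant.
1	108823470	108830221	loss	0.05
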