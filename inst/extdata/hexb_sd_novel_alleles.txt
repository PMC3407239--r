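# cDNA keys of the previously unpublished alleles in the packaged catalog
c.626C>T
c.926G>T
c.1451G>A
c.1242+1G>A
c.1082+5G>A
c.1169+5G>A
c.634C>A
c.146C>A
c.1260_1265delAGTTGA
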