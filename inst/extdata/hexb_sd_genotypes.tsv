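patient_id	genotype
SD1	[c.626C>T(p.T209I)]+ [c.299+1471_408del2406]
SD2	[c.1303_1304delGT(p.R435fsX20)]+ [c.926G>T(p.C309F)]
SD3	[c.1451G>A(p.G484E)]+[?]
SD4	[c.448A>C(p.T150P)]+ [16Kbdel]
SD5	[c.445+1G>A (r.0)]+[c.1451G>A(p.G484E)]
SD6	[c.445+1G>A (r.0)]+[c.1597C>T(p.R533C)]
SD7	[c.445+1G>A (r.0)]+[c.1242+1G>A (p.K390_K414delfsX7)]
SD8	[c.445+1G>A (r.0)]+[c.1242+1G>A (p.K390_K414delfsX7)]
SD9	[c.1082+5G>A(p.G301_W361delfsX10)]+ [c.1601G>A(p.C534Y)]
SD10	[c.1169+5G>A(p.E362_K390del)]+ [c.448A>C(p.T150P)]
SD11	[c.634C>A(p.H212N)]+ [c.634C>A(p.H212N)]
SD12	[c.1597C>T(p.R533C)]+ [c.1597C>T(p.R533C)]
SD13	[c.146C>A(p.S49X)]+ [c.146C>A(p.S49X)]
SD14	[c.1260_1265delAGTTGA(p.V421_E422del)]+ [c.1260_1265delAGTTGA(p.V421_E422del)]
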