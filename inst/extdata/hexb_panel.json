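{"name":"HEXB_MLPA_v1","size_tolerance":1.5,"probes":[{"probe_id":"HEXB_ex01","role":"target","gene":"HEXB","exon":1,"product_size":94},{"probe_id":"HEXB_ex02","role":"target","gene":"HEXB","exon":2,"product_size":102},{"probe_id":"HEXB_ex03","role":"target","gene":"HEXB","exon":3,"product_size":110},{"probe_id":"HEXB_ex04","role":"target","gene":"HEXB","exon":4,"product_size":118},{"probe_id":"HEXB_ex05","role":"target","gene":"HEXB","exon":5,"product_size":126},{"probe_id":"HEXB_ex06","role":"target","gene":"HEXB","exon":6,"product_size":134},{"probe_id":"HEXB_ex07","role":"target","gene":"HEXB","exon":7,"product_size":142},{"probe_id":"HEXB_ex08","role":"target","gene":"HEXB","exon":8,"product_size":150},{"probe_id":"HEXB_ex09","role":"target","gene":"HEXB","exon":9,"product_size":158},{"probe_id":"HEXB_ex10","role":"target","gene":"HEXB","exon":10,"product_size":166},{"probe_id":"HEXB_ex11","role":"target","gene":"HEXB","exon":11,"product_size":174},{"probe_id":"HEXB_ex12","role":"target","gene":"HEXB","exon":12,"product_size":182},{"probe_id":"HEXB_ex13","role":"target","gene":"HEXB","exon":13,"product_size":190},{"probe_id":"HEXB_ex14","role":"target","gene":"HEXB","exon":14,"product_size":198},{"probe_id":"REF_ACTR1a","role":"reference","gene":"ACTR1a","exon":null,"product_size":210},{"probe_id":"REF_AFAP","role":"reference","gene":"AFAP","exon":null,"product_size":218},{"probe_id":"REF_ALB","role":"reference","gene":"ALB","exon":null,"product_size":226}]}
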