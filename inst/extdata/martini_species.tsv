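species	bead_name	bead_class
POPC	CHO	head
POPC	PO4	phosphate
POPC	GL1	glycerol
POPC	GL2	glycerol
POPC	C1A	tailA
POPC	C2A	tailA
POPC	C3A	tailA
POPC	C4A	tailA
POPC	C1B	tailB
POPC	C2B	tailB
POPC	D3B	tailB
POPC	C4B	tailB
POPC	C5B	tailB
DPPC	CHO	head
DPPC	PO4	phosphate
DPPC	GL1	glycerol
DPPC	GL2	glycerol
DPPC	C1A	tailA
DPPC	C2A	tailA
DPPC	C3A	tailA
DPPC	C4A	tailA
DPPC	C1B	tailB
DPPC	C2B	tailB
DPPC	C3B	tailB
DPPC	C4B	tailB
POPE	NH3	head
POPE	PO4	phosphate
POPE	GL1	glycerol
POPE	GL2	glycerol
POPE	C1A	tailA
POPE	C2A	tailA
POPE	C3A	tailA
POPE	C4A	tailA
POPE	C1B	tailB
POPE	C2B	tailB
POPE	D3B	tailB
POPE	C4B	tailB
POPE	C5B	tailB
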