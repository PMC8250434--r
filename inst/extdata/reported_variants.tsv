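gene	cdna	protein
CSMD1	c.904C>T	p.R302C
PARP8	c.860G>A	p.R287H
ADAMTSL1	c.G848A	p.G283D
FNDC3B	c.686A>G	p.H229R
SCO2	c.518A>T	p.D173V
ZNF644	c.3266A>G	p.Y1089C
SLC39A5	c.758C>A	p.A253E
SLC39A5	c.577G>A	p.D193N
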