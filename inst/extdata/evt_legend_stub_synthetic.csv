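fine_code,group
101,aspen
102,mixed_aspen_conifer
110,warm_conifer
111,warm_conifer
112,warm_conifer
120,cool_conifer
121,cool_conifer
130,woodland
131,woodland
140,shrub
141,shrub
150,herbaceous
151,herbaceous
160,wetland
170,disturbed
171,disturbed
180,nonflammable
181,nonflammable
190,herbaceous
200,shrub
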