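{"M01":{"id":"M01","width":10,"height":10,"grid":[[0,0,0,0,1,0,0,0,1,0],[0,0,1,0,0,1,0,0,0,1],[0,0,1,1,0,0,0,1,1,0],[1,0,0,0,0,0,0,0,0,0],[0,0,0,0,0,0,0,0,0,0],[0,0,1,1,1,0,0,0,0,0],[1,0,1,0,1,0,1,0,0,0],[0,0,1,0,0,0,0,0,1,0],[0,0,0,0,0,0,1,0,0,0],[0,1,1,0,0,1,1,0,1,0]],"starts":[[2,0],[3,6],[2,8],[1,4],[1,0]],"target":[4,3]},"M02":{"id":"M02","width":10,"height":10,"grid":[[1,0,0,1,0,0,0,0,0,0],[1,0,0,0,0,1,0,0,0,0],[1,0,0,0,1,1,1,0,1,1],[0,0,0,1,0,0,1,1,0,0],[0,0,0,0,0,1,0,0,0,0],[0,0,0,0,0,0,1,0,1,0],[0,0,1,0,0,0,0,0,0,0],[0,0,1,0,1,1,0,0,0,0],[0,0,0,1,0,0,0,0,1,1],[0,0,0,0,1,1,0,0,0,0]],"starts":[[3,6],[6,9],[0,5],[5,0],[2,4]],"target":[2,5]},"M03":{"id":"M03","width":10,"height":10,"grid":[[0,0,1,0,0,0,0,1,1,1],[0,0,1,0,0,0,0,0,1,0],[0,0,0,0,0,0,0,0,1,1],[0,1,0,0,0,0,0,1,0,0],[0,0,1,1,1,1,0,0,0,0],[0,0,1,0,1,0,0,0,0,0],[0,0,1,0,0,0,0,0,0,0],[0,0,0,0,1,1,0,0,0,1],[0,1,0,1,1,0,0,0,1,0],[0,1,0,0,0,0,0,0,0,0]],"starts":[[4,1],[4,0],[1,4],[3,6],[3,0]],"target":[7,2]}}
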